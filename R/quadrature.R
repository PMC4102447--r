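# Dense-quadrature oracles for the two study systems.  These re-derive
# the toy energies in plain R from the construction parameters (kept
# deliberately independent of the C-level term evaluation, which the
# tests cross-check against them) and integrate the defining
# configuration integrals directly, so every sampled estimate has an
# exact reference.

smootherstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 + u * (-15 + 6 * u))
}

bump_fun <- function(x, a, halfwidth, center) {
  u <- (x - center) / halfwidth
  ifelse(abs(u) < 1, a * (1 - u^2)^2, 0)
}

wall_lo <- function(x, k, at) ifelse(x < at, 0.5 * k * (x - at)^2, 0)
wall_hi <- function(x, k, at) ifelse(x > at, 0.5 * k * (x - at)^2, 0)

# trapezoid weights
twts <- function(g) {
  n <- length(g)
  d <- diff(g)
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

# ---- ray system ------------------------------------------------------

# closures over the ray-system construction parameters
ray_parts <- function(system, conditions) {
  inf <- system$info
  stopifnot(inf$family == "ray_system")
  sw <- inf$switch_range
  list(
    u_r = function(r) bump_fun(r, -inf$depth, inf$halfwidth, inf$r0) +
      wall_lo(r, 20, 1) + wall_hi(r, 20, 27),
    S = function(r) smootherstep((r - sw[1]) / (sw[2] - sw[1])),
    cref = function(r) inf$c_closed + (inf$c_open - inf$c_closed) *
      smootherstep((r - sw[1]) / (sw[2] - sw[1])),
    k_th = function(r) inf$k_site_theta *
      (1 - smootherstep((r - sw[1]) / (sw[2] - sw[1]))),
    k_Th = function(r) inf$k_site_Theta *
      (1 - smootherstep((r - sw[1]) / (sw[2] - sw[1]))),
    u_th_extra = function(th) wall_lo(th, 2, 5) + wall_hi(th, 2, 175) -
      conditions$kT * log(pmax(sin(th * pi / 180), 1e-10)),
    k_conf = inf$k_conf, c_open = inf$c_open)
}

# independent R-side energy of the ray system (oracle for the C terms)
ray_energy <- function(system, r, theta, Theta, cc,
                       conditions = sim_conditions()) {
  p <- ray_parts(system, conditions)
  p$u_r(r) + 0.5 * p$k_conf * (cc - p$cref(r))^2 +
    0.5 * p$k_th(r) * (theta - 90)^2 + 0.5 * p$k_Th(r) * Theta^2 +
    p$u_th_extra(theta)
}

harm <- function(x, restr) 0.5 * restr$k * (x - restr$center)^2

#' Quadrature reference for the ray-system restraint decomposition
#'
#' Computes every staged PMF of the Woo-Roux route on the
#' generalized-coordinate study system by dense trapezoid quadrature of
#' the defining configuration integrals (no sampling): the
#' conformational PMFs in site and bulk, the translational angle PMFs
#' with the previous restraints imposed, the restrained separation PMF,
#' and from them the restraint free energies, S*, I*, K_bind and the
#' standard-state binding free energy.  The direct binding constant
#' `k_direct` integrates the same site configuration integral without
#' any decomposition; agreement of `k_bind` with `k_direct` is the
#' acceptance oracle for the assembly algebra.
#'
#' @param system A [make_ray_system()] potential.
#' @param conditions A [sim_conditions()].
#' @param n_r,n_ang,n_c Grid sizes per coordinate.
#' @return List with `profiles` (the staged [profile1d()]s),
#'   `components` (inputs of [k_bind()]), `k_bind`, `dg_bind_us`,
#'   `k_direct`, `dg_direct`.
#' @export
ray_quadrature_components <- function(system, conditions = sim_conditions(),
                                      n_r = 241, n_ang = 181, n_c = 181) {
  p <- ray_parts(system, conditions)
  pr <- system$info$protocol
  beta <- conditions$beta
  rest <- pr$restraints
  site <- pr$site_range
  rs <- seq(site[1], site[2], length.out = n_r)        # site separation grid
  rf <- seq(1, 27, length.out = 3 * n_r)               # full separation grid
  gth <- seq(5, 175, length.out = n_ang)
  gTh <- seq(-180, 180, length.out = 2 * n_ang)
  gc <- seq(-2, 9, length.out = n_c)
  wth <- twts(gth); wTh <- twts(gTh); wc <- twts(gc)

  # angular and conformational factors at fixed separation (the energy
  # factorizes over theta, Theta, c given r)
  I_th <- function(r, u_extra = 0 * gth) {
    E <- outer(r, gth, function(ri, th)
      0.5 * p$k_th(ri) * (th - 90)^2 + p$u_th_extra(th)) +
      matrix(u_extra, length(r), length(gth), byrow = TRUE)
    as.numeric(exp(-beta * E) %*% wth)
  }
  I_Th <- function(r, u_extra = 0 * gTh) {
    E <- outer(r, gTh, function(ri, Th) 0.5 * p$k_Th(ri) * Th^2) +
      matrix(u_extra, length(r), length(gTh), byrow = TRUE)
    as.numeric(exp(-beta * E) %*% wTh)
  }
  I_c <- function(r, u_extra = 0 * gc) {
    E <- outer(r, gc, function(ri, ci) 0.5 * p$k_conf * (ci - p$cref(ri))^2) +
      matrix(u_extra, length(r), length(gc), byrow = TRUE)
    as.numeric(exp(-beta * E) %*% wc)
  }
  wr_site <- twts(rs)
  b_r <- exp(-beta * p$u_r(rs))

  # conformational PMF in the bound ensemble (site separations only)
  f_c_site <- vapply(gc, function(ci) {
    sum(wr_site * b_r * I_th(rs) * I_Th(rs) *
          exp(-beta * 0.5 * p$k_conf * (ci - p$cref(rs))^2))
  }, numeric(1))
  w_site_c <- profile1d(gc, -conditions$kT * log(f_c_site), cv_name = "c")
  # conformational PMF in bulk: the decoupled conformational term
  w_bulk_c <- profile1d(gc, 0.5 * p$k_conf * (gc - p$c_open)^2, cv_name = "c")

  # theta PMF with the conformational restraint imposed
  Ic_uc <- I_c(rs, harm(gc, rest$c))
  f_th <- vapply(seq_along(gth), function(j) {
    sum(wr_site * b_r * I_Th(rs) * Ic_uc *
          exp(-beta * (0.5 * p$k_th(rs) * (gth[j] - 90)^2 +
                         p$u_th_extra(gth[j]))))
  }, numeric(1))
  w_theta <- profile1d(gth, -conditions$kT * log(f_th), cv_name = "theta")

  # Theta PMF with conformational + theta restraints imposed
  Ith_ut <- I_th(rs, harm(gth, rest$theta))
  f_Th <- vapply(seq_along(gTh), function(j) {
    sum(wr_site * b_r * Ith_ut * Ic_uc *
          exp(-beta * 0.5 * p$k_Th(rs) * gTh[j]^2))
  }, numeric(1))
  w_Theta <- profile1d(gTh, -conditions$kT * log(f_Th), cv_name = "Theta")

  # fully restrained separation PMF
  W_r <- profile1d(rf, p$u_r(rf) - conditions$kT *
                     log(I_th(rf, harm(gth, rest$theta)) *
                           I_Th(rf, harm(gTh, rest$Theta)) *
                           I_c(rf, harm(gc, rest$c))), cv_name = "r")

  comps <- list(
    dgc_site = restraint_dg_from_pmf(w_site_c, rest$c$center, rest$c$k,
                                     conditions),
    dgc_bulk = restraint_dg_from_pmf(w_bulk_c, rest$c$center, rest$c$k,
                                     conditions),
    dgo_alpha = 0, dgo_beta = 0, dgo_gamma = 0, dgo_bulk = 0,
    dgt_theta = restraint_dg_from_pmf(w_theta, rest$theta$center,
                                      rest$theta$k, conditions),
    dgt_Theta = restraint_dg_from_pmf(w_Theta, rest$Theta$center,
                                      rest$Theta$k, conditions),
    s_star = s_star(rest$theta, rest$Theta, pr$r_star, conditions),
    i_star = i_star(W_r, site, conditions, bulk_range = pr$bulk_range))
  kb <- k_bind(comps, conditions)

  # direct site configuration integral, no decomposition
  denom_c <- sum(wc * exp(-beta * 0.5 * p$k_conf * (gc - p$c_open)^2))
  k_direct <- pr$r_star^2 * (pi / 180)^2 *
    sum(wr_site * b_r * I_th(rs) * I_Th(rs) * I_c(rs)) / denom_c
  list(profiles = list(w_site_c = w_site_c, w_bulk_c = w_bulk_c,
                       w_theta = w_theta, w_Theta = w_Theta,
                       separation = W_r),
       components = comps, k_bind = kb,
       dg_bind_us = dg_bind_us(kb, conditions),
       k_direct = k_direct, dg_direct = dg_bind_us(k_direct, conditions))
}

# ---- Cartesian funnel system ----------------------------------------

# independent R-side energy of the funnel system at (x, y, z, c)
funnel_energy <- function(system, x, y, z, cc) {
  inf <- system$info
  stopifnot(inf$family == "funnel_system")
  site <- inf$site
  d <- sqrt((x - site[1])^2 + (y - site[2])^2 + (z - site[3])^2)
  sw <- inf$switch_range
  cref <- inf$c_closed + (inf$c_open - inf$c_closed) *
    smootherstep((d - sw[1]) / (sw[2] - sw[1]))
  e <- bump_fun(d, -inf$depth, inf$halfwidth, 0) +
    0.5 * inf$k_conf * (cc - cref)^2
  if (inf$profile_kind == "barrier")
    e <- e + bump_fun(d, attr_barrier(system), 2, inf$halfwidth + 2.3)
  e
}

attr_barrier <- function(system) {
  bt <- Filter(function(t) t$type == "radial_bump" && t$a > 0, system$terms)
  if (length(bt)) bt[[1]]$a else 0
}

#' Direct binding constant of the funnel study system
#'
#' The site configuration integral of the Cartesian system by dense
#' radial quadrature, `K = 4 pi int d^2 exp(-beta (G(d) - G(r*))) dd`
#' with `G(d)` the conformation-integrated radial free energy: the
#' quadrature reference for both the radial umbrella route and the
#' funnel metadynamics route.
#'
#' @param system A [make_funnel_system()] potential.
#' @param conditions A [sim_conditions()].
#' @param d_max Site integration limit (default the protocol's site
#'   range).
#' @return List with `k_bind`, `dg_bind_us` and the radial profile `G`.
#' @export
funnel_direct_kbind <- function(system, conditions = sim_conditions(),
                                d_max = NULL) {
  pr <- system$info$protocol
  if (is.null(d_max)) d_max <- pr$d_site_range[2]
  beta <- conditions$beta
  gd <- seq(1e-4, pr$r_star, length.out = 2001)
  gc <- seq(-2, 9, length.out = 181)
  wc <- twts(gc)
  site <- system$info$site
  # conformation-integrated radial free energy (evaluated on the axis;
  # the site terms depend only on the site distance)
  G <- vapply(gd, function(d) {
    E <- funnel_energy(system, site[1] + 0, site[2] + d, site[3], gc)
    -conditions$kT * log(sum(wc * exp(-beta * E)))
  }, numeric(1))
  Gb <- G[length(G)]
  sel <- gd <= d_max
  kb <- 4 * pi * trapz(gd[sel], gd[sel]^2 * exp(-beta * (G[sel] - Gb)))
  list(k_bind = kb, dg_bind_us = dg_bind_us(kb, conditions),
       G = profile1d(gd, G, align = FALSE, cv_name = "d_site"))
}

#' Quadrature reference FES of the funnel study system
#'
#' `F(x, c) = -kT log int exp(-beta (U + funnel wall)) dy dz` on a grid
#' over the axis projection and the conformational coordinate, by dense
#' radial quadrature over the funnel cross-section: the exact surface a
#' converged funnel metadynamics run should reproduce.
#'
#' @param system A [make_funnel_system()] potential.
#' @param funnel A [funnel_spec()].
#' @param conditions A [sim_conditions()].
#' @param x_grid,c_grid Evaluation grids.
#' @return A `free_energy_surface` (min-aligned).
#' @export
funnel_quadrature_fes <- function(system, funnel,
                                  conditions = sim_conditions(),
                                  x_grid = seq(2.6, 23.8, by = 0.1),
                                  c_grid = seq(-0.5, 5.5, by = 0.1)) {
  beta <- conditions$beta
  rho_max <- funnel$radius + 3
  grho <- seq(1e-4, rho_max, length.out = 301)
  wrho <- twts(grho)
  wallE <- wall_hi(grho, funnel$wall_constant, funnel$radius)
  pr <- system$info$protocol
  site <- system$info$site
  fe <- matrix(NA_real_, length(x_grid), length(c_grid))
  for (i in seq_along(x_grid)) {
    xw <- wall_lo(x_grid[i], 100, pr$rear_wall) +
      wall_hi(x_grid[i], 100, pr$far_wall)
    for (j in seq_along(c_grid)) {
      E <- funnel_energy(system, x_grid[i], site[2] + grho, site[3],
                         c_grid[j]) + wallE + xw
      fe[i, j] <- -conditions$kT *
        log(sum(wrho * 2 * pi * grho * exp(-beta * E)))
    }
  }
  fe <- fe - min(fe)
  structure(list(axes = list(x_grid, c_grid),
                 cv_names = c("sep_x", "spath_msd"),
                 free_energy = fe, visited = !is.na(fe), scale = NA_real_),
            class = "free_energy_surface")
}
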