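#' Cartesian funnel study system
#'
#' A point ligand at (x, y, z) with one conformational coordinate c: a
#' compact isotropic bound well of `depth` kcal/mol around the site point
#' (on the unbinding X-axis), an induced-fit switch that moves the
#' conformational reference from `c_closed` (bound) to `c_open` (bulk) as
#' the ligand leaves the site, and an exactly flat bulk.  A repulsive
#' wall behind the site closes the rear of the funnel and a far wall
#' bounds the separation at 24 A.  This is the system on which the
#' funnel-metadynamics route (2-D FES over separation x conformation,
#' minimum-free-energy path, standard-state correction) and the
#' radial umbrella-sampling route are compared: both measure the same
#' binding constant, which is also available by dense quadrature.
#'
#' The default protocol stored in `$info$protocol` carries the study
#' conditions: metadynamics CVs (axis projection on a 400-bin 0-24 A
#' grid, conformation on a 350-bin grid), the radial separation ladder
#' (0.5 A windows at k = 5 kcal/mol/A^2), the conformational ladders
#' (0.5-A^2 windows over 0-3 site / 0-5 bulk) and the restraint set.
#'
#' The potential itself is isotropic about the site (the ligand can
#' approach from any direction), so the radial umbrella route and the
#' quadrature oracle integrate clean spherical shells; the rear and far
#' walls that close the funnel column are part of the metadynamics-stage
#' restraints (stored in the protocol as `metad_walls`), not of the
#' physical system, exactly as the protein and the funnel play that role
#' in the all-atom setup.
#'
#' @param profile_kind `"flat"` (no unbinding barrier beyond the well
#'   edge) or `"barrier"` (an additional radial barrier ring).
#' @param depth Well depth, kcal/mol.
#' @param halfwidth Compact radial half-width of the well, A.
#' @param site Site centre on the X-axis.
#' @param k_conf,c_closed,c_open,switch_range Induced-fit coupling of the
#'   conformational coordinate to the site distance.
#' @param barrier_height For the barrier kind, `max - min` of the radial
#'   profile.
#' @return A 4-D [toy_potential()] (x, y, z, c).
#' @export
make_funnel_system <- function(profile_kind = c("flat", "barrier"),
                               depth = 8, halfwidth = 2.2,
                               site = c(5, 0, 0), k_conf = 2.5,
                               c_closed = 1, c_open = 4,
                               switch_range = c(3, 7),
                               barrier_height = 10) {
  profile_kind <- match.arg(profile_kind)
  if (depth <= 0) stop("well depth must be positive")
  terms <- list(
    list(type = "radial_bump", dims = 1:3, center = site, a = -depth,
         b = halfwidth, c = 0),
    list(type = "radial_switch_harmonic", dims = c(4L, 1:3), center = site,
         a = k_conf, b = c_closed, c = c_open,
         d = switch_range[1], e = switch_range[2]))
  if (profile_kind == "barrier") {
    if (barrier_height <= depth) stop("barrier_height must exceed depth")
    terms <- append(terms, list(
      list(type = "radial_bump", dims = 1:3, center = site,
           a = barrier_height - depth, b = 2, c = halfwidth + 2.3)), 1)
  }
  rear_wall <- site[1] - halfwidth - 0.3
  protocol <- list(
    site = site,
    rear_wall = rear_wall, far_wall = 24,
    metad_walls = list(
      list(type = "lower_wall", dims = 1L, a = 100, c = rear_wall),
      list(type = "upper_wall", dims = 1L, a = 100, c = 24),
      # keep the biased conformational CV inside its grid
      list(type = "lower_wall", dims = 4L, a = 10, c = -0.8),
      list(type = "upper_wall", dims = 4L, a = 10, c = 5.8)),
    cv_sep = metad_cv("sep_x", 1L, c(0, 24), 400),
    cv_conf = metad_cv("spath_msd", 4L, c(-1, 6), 350),
    sep_site_range = c(site[1] - halfwidth - 0.4, site[1] + halfwidth + 0.4),
    sep_bulk_range = c(18, 23),
    d_ladder = window_ladder(centers = c(0.15, 0.3, seq(0.5, 19, by = 0.5)),
                             k = 5, cv = "d_site"),
    r_star = 18,
    d_site_range = c(0.01, halfwidth + 0.8),
    c_ladder_site = window_ladder(from = -1, to = 3, spacing = 0.5, k = 2,
                                  cv = "c"),
    c_ladder_bulk = window_ladder(from = -1, to = 5, spacing = 0.5, k = 2,
                                  cv = "c"),
    restraints = list(c = list(center = c_closed, k = 4)))
  toy_potential(
    dimension = 4, terms = terms,
    domain_lower = c(-40, -40, -40, -5),
    domain_upper = c(40, 40, 40, 11),
    info = list(family = "funnel_system", profile_kind = profile_kind,
                depth = depth, halfwidth = halfwidth, site = site,
                k_conf = k_conf, c_closed = c_closed, c_open = c_open,
                switch_range = switch_range, protocol = protocol))
}

#' Generalized-coordinate ray study system for the restraint decomposition
#'
#' The full Woo-Roux staging needs the separation r, the two
#' translational angles (theta, Theta) and a conformational coordinate c.
#' This system carries them as explicit coordinates: r in A, theta and
#' Theta in degrees (Theta periodic), c in A^2, with the solid-angle
#' Jacobian `-kT log sin(theta)` folded into the effective potential so
#' that flat-measure Langevin sampling reproduces the spherical measure.
#' The site consists of a compact radial well at `r0 = 5` A (the bulk
#' reference point of the anchor geometry), a harmonic angular
#' confinement around (theta = 90, Theta = 0) degrees that fades away in
#' bulk, and the induced-fit conformational switch.  The transverse
#' Jacobian scale is fixed at the bulk reference separation `r_star`, so
#' the configuration volume element is `r_star^2 sin(theta) dr dtheta
#' dTheta` (radian measure) and the Woo-Roux identity
#' `K_bind = S* I* exp(-beta [...])` is exact; dense quadrature of the
#' same integral is the acceptance oracle.
#'
#' @param depth Well depth, kcal/mol.
#' @param r0 Bound separation, A.
#' @param halfwidth Radial half-width of the well, A.
#' @param k_conf,c_closed,c_open Conformational coupling (A^2 scale).
#' @param switch_range Separation interval of the induced-fit switch.
#' @param k_site_theta,k_site_Theta Site angular confinement,
#'   kcal/mol/deg^2.
#' @param conditions A [sim_conditions()] (sets the Jacobian magnitude).
#' @return A 4-D [toy_potential()] (r, theta, Theta, c) with the staging
#'   protocol in `$info$protocol`.
#' @export
make_ray_system <- function(depth = 7, r0 = 5, halfwidth = 1.5,
                            k_conf = 2.5, c_closed = 1, c_open = 4,
                            switch_range = c(6, 10),
                            k_site_theta = 0.004, k_site_Theta = 0.004,
                            conditions = sim_conditions()) {
  if (depth <= 0) stop("well depth must be positive")
  terms <- list(
    list(type = "bump", dims = 1L, a = -depth, b = halfwidth, c = r0),
    list(type = "switch_harmonic", dims = c(4L, 1L), a = k_conf,
         b = c_closed, c = c_open, d = switch_range[1], e = switch_range[2]),
    list(type = "fade_harmonic", dims = c(2L, 1L), a = k_site_theta, b = 90,
         d = switch_range[1], e = switch_range[2]),
    list(type = "fade_harmonic", dims = c(3L, 1L), a = k_site_Theta, b = 0,
         d = switch_range[1], e = switch_range[2]),
    list(type = "log_sin", dims = 2L, a = conditions$kT, b = pi / 180),
    list(type = "lower_wall", dims = 1L, a = 20, c = 1),
    list(type = "upper_wall", dims = 1L, a = 20, c = 27),
    list(type = "lower_wall", dims = 2L, a = 2, c = 5),
    list(type = "upper_wall", dims = 2L, a = 2, c = 175))
  protocol <- list(
    r0 = r0,
    restraints = list(
      c = list(center = c_closed, k = 4),
      theta = list(center = 90, k = 0.02),
      Theta = list(center = 0, k = 0.02),
      alpha = list(center = 90, k = 0),
      beta = list(center = 0, k = 0),
      gamma = list(center = 0, k = 0)),
    sep_ladder = window_ladder(from = 4, to = 25, spacing = 0.5, k = 5,
                               cv = "r"),
    c_ladder_site = window_ladder(from = -1, to = 3, spacing = 0.5, k = 2,
                                  cv = "c"),
    c_ladder_bulk = window_ladder(from = -1, to = 5, spacing = 0.5, k = 2,
                                  cv = "c"),
    r_pin_bulk = list(center = 24, k = 5),
    r_star = 24,
    site_range = c(r0 - halfwidth - 0.3, r0 + halfwidth + 0.5),
    bulk_range = c(22, 25),
    theta_range = c(40, 140),
    Theta_range = c(-70, 70))
  toy_potential(
    dimension = 4, terms = terms,
    domain_lower = c(0, 0, -180, -5),
    domain_upper = c(28, 180, 180, 11),
    info = list(family = "ray_system", depth = depth, r0 = r0,
                halfwidth = halfwidth, k_conf = k_conf,
                c_closed = c_closed, c_open = c_open,
                switch_range = switch_range,
                k_site_theta = k_site_theta, k_site_Theta = k_site_Theta,
                protocol = protocol),
    periodic = list(dims = 3L, lo = -180, hi = 180))
}
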