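#' Default run configuration
#'
#' A fully serializable description of an end-to-end toy experiment:
#' system family and construction arguments, thermodynamic conditions,
#' metadynamics stage (funnel geometry, schedule, run length) and
#' umbrella/ABF stage (window lengths, WHAM settings).  A run is
#' reproducible from its configuration and seed alone.
#'
#' @param system System family: `"funnel_system"`, `"ray_system"`,
#'   `"binding_landscape"` or `"double_well"`.
#' @param seed Integer master seed.
#' @param ... Construction arguments forwarded to the system constructor.
#' @return A nested list (class `run_config`).
#' @export
default_config <- function(system = "funnel_system", seed = 1, ...) {
  structure(list(
    seed = as.integer(seed),
    temperature = 310,
    system = list(family = system, args = list(...)),
    metad = list(radius = 15, wall_constant = 100, omega = 1, tau = 1,
                 delta_T = 3100, sigmas = c(0.4, 0.1),
                 timestep = 0.001, friction = 0.1, n_steps = 2e7,
                 save_stride = 500, avg_start = 0.3,
                 bound_threshold = 8, unbound_threshold = 18,
                 min_recrossings = 3),
    us = list(pmf_source = "sampled", timestep = 0.005, friction = 1,
              n_steps_window = 6e5, save_stride = 10, burn_in = 0.5,
              abf_steps = 2e6, abf_bin = 1, ramp = 200,
              abf_timestep = 0.002, abf_friction = 0.05,
              wham_bins = 200, wham_tol = 1e-7)),
    class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_config()` returns the `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Conditions and system described by a run configuration
#'
#' @param config A `run_config`.
#' @param conditions A [sim_conditions()].
#' @return `config_conditions()` the [sim_conditions()];
#'   `build_system()` the configured [toy_potential()].
#' @export
config_conditions <- function(config) sim_conditions(config$temperature)

#' @rdname config_conditions
#' @export
build_system <- function(config, conditions = config_conditions(config)) {
  fam <- config$system$family
  args <- config$system$args %||% list()
  switch(fam,
    funnel_system = do.call(make_funnel_system, args),
    ray_system = do.call(make_ray_system,
                         c(args, list(conditions = conditions))),
    binding_landscape = do.call(make_binding_landscape, args),
    double_well = do.call(make_double_well, args),
    stop("unknown system family: ", fam))
}

#' Run the funnel metadynamics route end to end
#'
#' Builds the configured system, runs well-tempered funnel metadynamics
#' over (separation, conformation), reconstructs the 2-D free energy
#' surface, extracts the minimum-free-energy pathway, and reports the
#' dissociation barrier and the standard-state corrected binding free
#' energy, plus the unbind/rebind recrossing count as the convergence
#' diagnostic.  With `outdir` set, writes `HILLS`, `fes.dat`,
#' `minpath.dat` and `metad_report.txt`.
#'
#' @param config A [default_config()] for a `funnel_system`.
#' @param outdir Optional output directory.
#' @param conditions Simulation conditions (from the config temperature
#'   by default).
#' @return List with `hills_log`, `trajectory`, `fes`, `min_path`,
#'   `dg_bind_meta`, `dg_off`, `depth`, `recrossings`, `converged`,
#'   `funnel`.
#' @export
metad_route <- function(config, outdir = NULL,
                        conditions = config_conditions(config)) {
  sys <- build_system(config, conditions)
  pr <- sys$info$protocol
  if (is.null(pr$cv_sep)) stop("metad_route needs a funnel_system config")
  mc <- config$metad
  funnel <- funnel_spec(radius = mc$radius, wall_constant = mc$wall_constant,
                        origin = pr$site, direction = c(1, 0, 0))
  schedule <- wt_schedule(omega = mc$omega, tau = mc$tau,
                          delta_T = mc$delta_T, sigmas = mc$sigmas)
  params <- langevin_params(timestep = mc$timestep, friction = mc$friction,
                            n_steps = mc$n_steps, seed = config$seed,
                            save_stride = mc$save_stride)
  x0 <- c(pr$site, sys$info$c_closed)
  run <- run_metad(sys, list(pr$cv_sep, pr$cv_conf), schedule, params,
                   conditions, funnel = funnel,
                   extra_restraints = pr$metad_walls, x0 = x0,
                   avg_start = mc$avg_start)
  fes <- reconstruct_fes(run$hills_log, conditions)
  path <- min_free_energy_path(crop_fes(fes))
  dgm <- dg_bind_meta(path, funnel, pr$sep_site_range, pr$sep_bulk_range,
                      conditions)
  off <- dg_off(path, pr$sep_site_range)
  rec <- recrossing_count(run$trajectory$cv_values[, 1],
                          mc$bound_threshold, mc$unbound_threshold)
  out <- list(hills_log = run$hills_log, trajectory = run$trajectory,
              fes = fes, min_path = path,
              dg_bind_meta = as.numeric(dgm),
              correction = attr(dgm, "correction"),
              depth = attr(dgm, "depth"), dg_off = off,
              recrossings = rec, converged = rec >= mc$min_recrossings,
              funnel = funnel, seed = config$seed)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_hills(run$hills_log, file.path(outdir, "HILLS"))
    write_fes(fes, file.path(outdir, "fes.dat"))
    write_pmf(path, file.path(outdir, "minpath.dat"))
    writeLines(c(
      sprintf("seed %d", config$seed),
      sprintf("funnel_radius %g", mc$radius),
      sprintf("recrossings %d", rec),
      sprintf("converged %s", rec >= mc$min_recrossings),
      sprintf("depth %.6f", out$depth),
      sprintf("dg_off %.6f", off),
      sprintf("dg_bind_meta %.6f", out$dg_bind_meta)),
      file.path(outdir, "metad_report.txt"))
  }
  out
}

us_params <- function(config, seed_offset, n_steps = NULL) {
  uc <- config$us
  langevin_params(timestep = uc$timestep, friction = uc$friction,
                  n_steps = n_steps %||% uc$n_steps_window,
                  seed = config$seed + seed_offset,
                  save_stride = uc$save_stride)
}

harm_term <- function(dim, restr)
  list(type = "harmonic", dims = as.integer(dim), a = restr$k,
       c = restr$center)

#' Run the umbrella-sampling / ABF restraint route end to end
#'
#' Executes the staged restraint protocol of the configured system in
#' the published order — conformational umbrella sampling in site and
#' bulk, then (for the generalized-coordinate system) adaptive biasing
#' force on the translational angles with the previous restraints
#' imposed, then the restrained separation ladder — unbiases every stage
#' (WHAM for umbrella stages, mean-force integration for ABF), converts
#' the staged PMFs into restraint free energies, and assembles S*, I*,
#' K_bind and the standard-state binding free energy.  With
#' `pmf_source = "quadrature"` in the config, the staged PMFs are
#' replaced by their dense-quadrature references (no sampling), which
#' isolates the assembly algebra.
#'
#' @param config A [default_config()] for a `funnel_system` (radial
#'   route, no angular restraints) or `ray_system` (full Woo-Roux
#'   staging).
#' @param outdir Optional output directory for per-stage PMFs and the
#'   component report.
#' @param conditions Simulation conditions.
#' @return List with `components`, `k_bind`, `dg_bind_us`, `profiles`
#'   and per-stage diagnostics.
#' @export
us_route <- function(config, outdir = NULL,
                     conditions = config_conditions(config)) {
  sys <- build_system(config, conditions)
  fam <- sys$info$family
  res <- if (identical(config$us$pmf_source, "quadrature")) {
    if (fam == "ray_system") {
      q <- ray_quadrature_components(sys, conditions)
      list(components = q$components, k_bind = q$k_bind,
           dg_bind_us = q$dg_bind_us, profiles = q$profiles,
           k_direct = q$k_direct, dg_direct = q$dg_direct)
    } else stop("quadrature PMF source is available for the ray_system")
  } else if (fam == "ray_system") {
    us_route_ray(sys, config, conditions)
  } else if (fam == "funnel_system") {
    us_route_radial(sys, config, conditions)
  } else stop("us_route needs a funnel_system or ray_system config")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res$profiles))
      write_pmf(res$profiles[[nm]], file.path(outdir, paste0(nm, ".dat")))
    keyvals <- c(res$components,
                 list(k_bind = res$k_bind, dg_bind_us = res$dg_bind_us,
                      seed = config$seed))
    writeLines(paste(names(keyvals),
                     vapply(keyvals, function(v) num17(v), character(1))),
               file.path(outdir, "us_report.txt"))
  }
  res
}

# full Woo-Roux staging on the generalized-coordinate system
us_route_ray <- function(sys, config, conditions) {
  pr <- sys$info$protocol
  uc <- config$us
  rest <- pr$restraints
  r0 <- pr$r0
  c0 <- rest$c$center
  bound <- c(r0, 90, 0, c0)

  # stage 1: conformational PMF in the bound site.  A soft wall at the
  # outer site boundary pins the ensemble to the site region (the site
  # definition of the decomposition) while high-c windows flatten the
  # unbinding barrier.
  site_wall <- list(type = "upper_wall", dims = 1L, a = 10,
                    c = pr$site_range[2])
  lad <- pr$c_ladder_site
  x0 <- do.call(rbind, lapply(lad$centers, function(ce) c(r0, 90, 0, ce)))
  lad <- run_umbrella(sys, 4L, lad, us_params(config, 1), conditions,
                      extra_restraints = list(site_wall), x0_frames = x0,
                      burn_in = uc$burn_in)
  w_site_c <- wham(lad, uc$wham_bins, uc$wham_tol, conditions)$pmf

  # stage 2: conformational PMF in bulk (separation pinned far out)
  lad <- pr$c_ladder_bulk
  pin <- harm_term(1L, pr$r_pin_bulk)
  x0 <- do.call(rbind, lapply(lad$centers, function(ce)
    c(pr$r_pin_bulk$center, 90, 0, ce)))
  lad <- run_umbrella(sys, 4L, lad, us_params(config, 2), conditions,
                      extra_restraints = list(pin), x0_frames = x0,
                      burn_in = uc$burn_in)
  w_bulk_c <- wham(lad, uc$wham_bins, uc$wham_tol, conditions)$pmf

  # stages 3-4: ABF on the translational angles with the previous
  # restraints imposed.  The angular coordinates carry degree units, so
  # they get a lighter friction (faster angular diffusion) and a
  # correspondingly smaller timestep.
  abf_params <- function(offset)
    langevin_params(timestep = uc$abf_timestep, friction = uc$abf_friction,
                    n_steps = uc$abf_steps, seed = config$seed + offset,
                    save_stride = uc$save_stride)
  restr_c <- harm_term(4L, rest$c)
  abf_th <- run_abf(sys, 2L, pr$theta_range, abf_params(3), conditions,
                    bin_width = uc$abf_bin, ramp_threshold = uc$ramp,
                    extra_restraints = list(restr_c), x0 = bound)
  restr_th <- harm_term(2L, rest$theta)
  abf_Th <- run_abf(sys, 3L, pr$Theta_range, abf_params(4), conditions,
                    bin_width = uc$abf_bin, ramp_threshold = uc$ramp,
                    extra_restraints = list(restr_c, restr_th), x0 = bound)

  # stage 5: restrained separation ladder
  restr_Th <- harm_term(3L, rest$Theta)
  lad <- pr$sep_ladder
  x0 <- do.call(rbind, lapply(lad$centers, function(ce) c(ce, 90, 0, c0)))
  lad <- run_umbrella(sys, 1L, lad, us_params(config, 5), conditions,
                      extra_restraints = list(restr_c, restr_th, restr_Th),
                      x0_frames = x0, burn_in = uc$burn_in)
  sep <- wham(lad, max(uc$wham_bins, 210), uc$wham_tol, conditions)$pmf

  comps <- list(
    dgc_site = restraint_dg_from_pmf(w_site_c, rest$c$center, rest$c$k,
                                     conditions, boundary_tol = 1e-4),
    dgc_bulk = restraint_dg_from_pmf(w_bulk_c, rest$c$center, rest$c$k,
                                     conditions, boundary_tol = 1e-4),
    dgo_alpha = 0, dgo_beta = 0, dgo_gamma = 0, dgo_bulk = 0,
    dgt_theta = restraint_dg_from_pmf(abf_th$pmf, rest$theta$center,
                                      rest$theta$k, conditions,
                                      boundary_tol = 1e-4),
    dgt_Theta = restraint_dg_from_pmf(abf_Th$pmf, rest$Theta$center,
                                      rest$Theta$k, conditions,
                                      boundary_tol = 1e-4),
    s_star = s_star(rest$theta, rest$Theta, pr$r_star, conditions),
    i_star = i_star(sep, pr$site_range, conditions,
                    bulk_range = pr$bulk_range))
  kb <- k_bind(comps, conditions)
  list(components = comps, k_bind = kb,
       dg_bind_us = dg_bind_us(kb, conditions),
       profiles = list(w_site_c = w_site_c, w_bulk_c = w_bulk_c,
                       w_theta = abf_th$pmf, w_Theta = abf_Th$pmf,
                       separation = sep),
       abf = list(theta = abf_th$estimator, Theta = abf_Th$estimator))
}

# radial (isotropic, restraint-free angles) route on the Cartesian system
us_route_radial <- function(sys, config, conditions) {
  pr <- sys$info$protocol
  uc <- config$us
  rest <- pr$restraints
  site <- pr$site
  c0 <- rest$c$center

  # conformational PMFs in site and bulk.  The spherical wall at the
  # outer site boundary is the site definition of the decomposition; it
  # keeps the ligand bound while high-c windows flatten the barrier.
  site_wall <- list(type = "cylinder_wall", dims = 1:3, center = site,
                    a = 10, b = pr$d_site_range[2])
  lad <- pr$c_ladder_site
  x0 <- do.call(rbind, lapply(lad$centers, function(ce) c(site, ce)))
  lad <- run_umbrella(sys, 4L, lad, us_params(config, 1), conditions,
                      extra_restraints = list(site_wall), x0_frames = x0,
                      burn_in = uc$burn_in)
  w_site_c <- wham(lad, uc$wham_bins, uc$wham_tol, conditions)$pmf

  dpin <- list(type = "radial_harmonic", dims = 1:3, center = site,
               a = 5, c = pr$r_star)
  lad <- pr$c_ladder_bulk
  x0 <- do.call(rbind, lapply(lad$centers, function(ce)
    c(site + c(pr$r_star, 0, 0), ce)))
  lad <- run_umbrella(sys, 4L, lad, us_params(config, 2), conditions,
                      extra_restraints = list(dpin), x0_frames = x0,
                      burn_in = uc$burn_in)
  w_bulk_c <- wham(lad, uc$wham_bins, uc$wham_tol, conditions)$pmf

  # restrained radial separation ladder; the raw distance PMF keeps the
  # 2 kT log(d) shell Jacobian and is referenced at r*, whose r*^2 lives
  # in S* (= 4 pi r*^2 with no angular restraints)
  restr_c <- harm_term(4L, rest$c)
  ucv <- umbrella_cv_radial(1:3, site)
  lad <- pr$d_ladder
  x0 <- do.call(rbind, lapply(lad$centers, function(ce)
    c(site + c(ce, 0, 0), c0)))
  lad <- run_umbrella(sys, ucv, lad, us_params(config, 3), conditions,
                      extra_restraints = list(restr_c), x0_frames = x0,
                      burn_in = uc$burn_in)
  sep <- wham(lad, max(uc$wham_bins, 200), uc$wham_tol, conditions)$pmf

  zero <- list(center = 90, k = 0)
  comps <- list(
    dgc_site = restraint_dg_from_pmf(w_site_c, rest$c$center, rest$c$k,
                                     conditions, boundary_tol = 1e-4),
    dgc_bulk = restraint_dg_from_pmf(w_bulk_c, rest$c$center, rest$c$k,
                                     conditions, boundary_tol = 1e-4),
    dgo_alpha = 0, dgo_beta = 0, dgo_gamma = 0, dgo_bulk = 0,
    dgt_theta = 0, dgt_Theta = 0,
    s_star = s_star(zero, list(center = 0, k = 0), pr$r_star, conditions),
    i_star = i_star(sep, pr$d_site_range, conditions, r_star = pr$r_star))
  kb <- k_bind(comps, conditions)
  list(components = comps, k_bind = kb,
       dg_bind_us = dg_bind_us(kb, conditions),
       profiles = list(w_site_c = w_site_c, w_bulk_c = w_bulk_c,
                       separation = sep))
}
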