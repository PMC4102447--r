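#' Well-tempered metadynamics schedule
#'
#' Deposition schedule for well-tempered metadynamics: an initial hill
#' height `omega` deposited every `tau` ps, with the height scaled by
#' `exp(-V / (kB * delta_T))` at the current bias `V`.  The defaults are
#' the published kinase-unbinding settings: omega = 1 kcal/mol at 1 hill
#' per ps (a deposition rate of 1 kcal/mol/ps), delta_T = 3100 K, i.e. a
#' bias factor delta_T / T = 10 at 310 K.
#'
#' @param omega Initial hill height, kcal/mol (> 0).
#' @param tau Deposition interval, ps.
#' @param delta_T Well-tempered boost temperature, K (> 0, may be `Inf`
#'   for standard metadynamics).  Authoritative when both `delta_T` and
#'   `bias_factor` are given.
#' @param bias_factor Alternative specification, `delta_T / temperature`
#'   (the convention in which the published 3100 K corresponds to 10 at
#'   310 K); resolved against the run's conditions.
#' @param sigmas Gaussian hill widths, one per collective variable, in the
#'   CV's units (defaults 0.4 A for the separation CV and 0.05 A^2 for the
#'   path-MSD CV).
#' @return An object of class `wt_schedule`.
#' @export
wt_schedule <- function(omega = 1, tau = 1, delta_T = 3100,
                        bias_factor = NULL, sigmas = c(0.4, 0.05)) {
  if (omega <= 0) stop("omega must be positive")
  if (tau <= 0) stop("tau must be positive")
  if (is.null(delta_T) && is.null(bias_factor))
    stop("give delta_T or bias_factor")
  if (!is.null(delta_T) && delta_T <= 0) stop("delta_T must be positive")
  structure(list(omega = omega, tau = tau, delta_T = delta_T,
                 bias_factor = bias_factor, sigmas = sigmas),
            class = "wt_schedule")
}

resolve_delta_T <- function(schedule, conditions) {
  if (!is.null(schedule$delta_T)) return(schedule$delta_T)
  schedule$bias_factor * conditions$temperature
}

#' Well-tempered hill height
#'
#' `height = omega * exp(-V / (kB * delta_T))` at accumulated bias `V`:
#' the first hill has the full height `omega`, and heights decay towards
#' zero as the bias fills the landscape.
#'
#' @param bias_at_center Accumulated bias at the deposition point,
#'   kcal/mol (>= 0).
#' @param schedule A [wt_schedule()].
#' @param conditions A [sim_conditions()] (supplies kB, and T if the
#'   schedule was given as a bias factor).
#' @return Height in kcal/mol, in (0, omega\].
#' @examples
#' s <- wt_schedule()
#' wt_hill_height(1, s, sim_conditions())  # exp(-1/6.1603) ~ 0.850
#' @export
wt_hill_height <- function(bias_at_center, schedule, conditions = sim_conditions()) {
  if (any(bias_at_center < 0)) stop("bias value must be non-negative")
  dT <- resolve_delta_T(schedule, conditions)
  schedule$omega * exp(-bias_at_center / (conditions$boltzmann_constant * dT))
}

#' Cylindrical funnel restraint
#'
#' A one-sided harmonic wall at perpendicular distance `radius` from the
#' unbinding axis, confining the unbound ligand to a column of
#' cross-section pi * radius^2 so that the binding free energy can be
#' referenced to the standard concentration.  Defaults are the published
#' values: radius 15 A, elastic constant 100 kcal/mol/A^2.
#'
#' @param radius Cylinder radius, A (> 0).
#' @param wall_constant Elastic constant, kcal/mol/A^2.
#' @param origin Point on the axis.
#' @param direction Axis direction; the samplers require it to be a
#'   coordinate axis of the toy system.
#' @return An object of class `funnel_spec`.
#' @export
funnel_spec <- function(radius = 15, wall_constant = 100,
                        origin = c(0, 0, 0), direction = c(1, 0, 0)) {
  if (radius <= 0) stop("radius must be positive")
  if (wall_constant < 0) stop("wall_constant must be non-negative")
  structure(list(radius = radius, wall_constant = wall_constant,
                 origin = origin, direction = direction / sqrt(sum(direction^2))),
            class = "funnel_spec")
}

#' Funnel wall energy at a position
#'
#' Zero inside the cylinder; `(k/2) (d - R)^2` outside, with `d` the
#' perpendicular distance from the axis.
#'
#' @param position 3-D point.
#' @param funnel A [funnel_spec()].
#' @return Energy in kcal/mol.
#' @export
funnel_wall_energy <- function(position, funnel) {
  d <- funnel_radial(position, funnel$origin, funnel$direction)
  if (d <= funnel$radius) return(0)
  0.5 * funnel$wall_constant * (d - funnel$radius)^2
}

# funnel as a C-level wall term acting on the two coordinates
# perpendicular to its (axis-aligned) direction
funnel_term <- function(funnel, dimension) {
  if (is.null(funnel)) return(NULL)
  ax <- which(abs(abs(funnel$direction) - 1) < 1e-9)
  if (length(ax) != 1)
    stop("the sampler requires the funnel axis along a coordinate axis")
  perp <- setdiff(1:3, ax)
  if (dimension < max(perp)) stop("potential has too few coordinates for a funnel")
  list(type = "cylinder_wall", dims = as.integer(perp),
       center = funnel$origin[perp], a = funnel$wall_constant,
       b = funnel$radius)
}

#' Declare a metadynamics collective variable
#'
#' The toy samplers bias coordinate projections: each CV is one
#' coordinate of the toy potential together with its grid (range and bin
#' count) for bias accumulation and FES output.
#'
#' @param name CV label (e.g. `"com_distance"`, `"spath_msd"`).
#' @param dim Coordinate index in the toy potential.
#' @param range Length-2 grid range in CV units.
#' @param bins Number of grid bins (defaults: 400 bins over 0-24 A for a
#'   separation CV as published; pass 350 over 0-6 A^2 for the path CV).
#' @return A `metad_cv` list.
#' @export
metad_cv <- function(name, dim, range = c(0, 24), bins = 400) {
  stopifnot(length(range) == 2, range[2] > range[1], bins >= 2)
  structure(list(name = name, dim = as.integer(dim),
                 range = as.numeric(range), bins = as.integer(bins)),
            class = "metad_cv")
}

#' Run well-tempered (funnel) metadynamics on a toy potential
#'
#' Overdamped Langevin dynamics on `potential` plus the history-dependent
#' Gaussian bias and, optionally, the funnel wall.  Hills are deposited
#' every `schedule$tau` ps at the current CV position with the
#' well-tempered height scaling; the bias and its gradient are
#' accumulated on the declared CV grid (6-sigma cutoff) and interpolated
#' during dynamics.  Depositions falling outside the grid are clamped to
#' the edge and counted.
#'
#' @param potential A [toy_potential()].
#' @param cvs List of one or two [metad_cv()] declarations.
#' @param schedule A [wt_schedule()] (its `sigmas` must match the CV count).
#' @param params A [langevin_params()].
#' @param conditions A [sim_conditions()].
#' @param funnel Optional [funnel_spec()] (requires a >= 3-D potential).
#' @param extra_restraints Optional list of additional potential terms
#'   active during the run (e.g. the rear/far walls closing the funnel
#'   column).
#' @param x0 Initial coordinates.
#' @param avg_start Fraction of the deposition schedule after which bias
#'   grids are averaged for the FES estimator (default 0.5).
#' @return A list with `hills_log` (a `hills_log`) and `trajectory` (a
#'   `toy_trajectory` whose `cv_values` are the CV time series).
#' @export
run_metad <- function(potential, cvs, schedule, params,
                      conditions = sim_conditions(), funnel = NULL,
                      extra_restraints = NULL, x0 = NULL, avg_start = 0.5) {
  stopifnot(inherits(schedule, "wt_schedule"))
  if (inherits(cvs, "metad_cv")) cvs <- list(cvs)
  ncv <- length(cvs)
  if (length(schedule$sigmas) != ncv)
    stop("schedule has ", length(schedule$sigmas), " sigma(s) for ", ncv, " CV(s)")
  if (is.null(x0)) {
    lo <- ifelse(is.finite(potential$domain_lower), potential$domain_lower, -1)
    hi <- ifelse(is.finite(potential$domain_upper), potential$domain_upper, 1)
    x0 <- (lo + hi) / 2
  }
  terms <- c(potential$terms, extra_restraints)
  ft <- funnel_term(funnel, potential$dimension)
  if (!is.null(ft)) terms <- c(terms, list(ft))
  dT <- resolve_delta_T(schedule, conditions)
  kT <- conditions$boltzmann_constant * conditions$temperature
  tau_steps <- max(1L, as.integer(round(schedule$tau / params$timestep)))
  res <- with_seed(params$seed,
    cpp_metad(terms, as.numeric(x0), params$timestep, params$friction,
              params$n_steps, params$save_stride, kT,
              vapply(cvs, function(cv) cv$dim, integer(1)),
              vapply(cvs, function(cv) cv$range[1], numeric(1)),
              vapply(cvs, function(cv) cv$range[2], numeric(1)),
              vapply(cvs, function(cv) cv$bins, integer(1)),
              schedule$sigmas, schedule$omega, tau_steps,
              conditions$boltzmann_constant * dT, avg_start,
              potential$domain_lower, potential$domain_upper, 10,
              pot_wrap(potential)))
  hills <- as.data.frame(res$hills)
  cvn <- vapply(cvs, function(cv) cv$name, character(1))
  names(hills) <- c("time", paste0("center_", cvn), paste0("sigma_", cvn),
                    "height")
  log <- structure(list(
    schedule = schedule, hills = hills, cv_names = cvn,
    cv_ranges = lapply(cvs, function(cv) cv$range),
    bin_counts = vapply(cvs, function(cv) cv$bins, integer(1)),
    delta_T = dT, temperature = conditions$temperature,
    bias_final = res$bias_final, bias_avg = res$bias_avg,
    n_avg = res$n_avg, n_clamped = res$n_clamped), class = "hills_log")
  traj <- structure(list(times = res$times, coords = res$coords,
                         cv_values = {
                           cvv <- res$cv_traj
                           colnames(cvv) <- cvn
                           cvv
                         }), class = "toy_trajectory")
  list(hills_log = log, trajectory = traj)
}

#' @export
print.hills_log <- function(x, ...) {
  cat(sprintf("Well-tempered hills log: %d hills on %d CV(s) [%s]\n",
              nrow(x$hills), length(x$cv_names),
              paste(x$cv_names, collapse = ", ")))
  cat(sprintf("  delta_T = %g K, omega = %g kcal/mol, final height = %.4g\n",
              x$delta_T, x$schedule$omega, utils::tail(x$hills$height, 1)))
  if (x$n_clamped > 0)
    cat(sprintf("  %d depositions clamped to the grid edge\n", x$n_clamped))
  invisible(x)
}

grid_centers <- function(range, bins) {
  range[1] + (seq_len(bins) - 0.5) * diff(range) / bins
}

#' Total metadynamics bias at a point
#'
#' Sum over deposited hills of
#' `height * exp(-sum_cv (s - center)^2 / (2 sigma^2))`; zero for an
#' empty log.
#'
#' @param point Numeric vector of CV values (or matrix, one point per row).
#' @param log A `hills_log` (or bare hills data frame in the same layout).
#' @return Bias in kcal/mol per point.
#' @export
bias_value <- function(point, log) {
  hills <- if (inherits(log, "hills_log")) log$hills else log
  if (is.null(dim(point))) point <- matrix(point, nrow = 1)
  if (nrow(hills) == 0) return(rep(0, nrow(point)))
  ncv <- (ncol(hills) - 2) / 2
  centers <- as.matrix(hills[, 1 + seq_len(ncv), drop = FALSE])
  sigmas <- as.matrix(hills[, 1 + ncv + seq_len(ncv), drop = FALSE])
  cpp_eval_hills(centers, sigmas, hills$height, as.matrix(point))
}

#' Reconstruct the free energy surface from a hills log
#'
#' The well-tempered estimator `F(s) = -((T + delta_T) / delta_T) V(s)`
#' evaluated on the declared grid and shifted so the minimum over visited
#' bins is zero.  `source = "avg"` uses the bias averaged over the second
#' half of the deposition schedule (lower estimator noise), `"final"` the
#' last bias, `"hills"` a fresh summation over the hill list (the path
#' used when a log has been re-read from file).
#'
#' @param log A `hills_log`.
#' @param conditions A [sim_conditions()].
#' @param source One of `"avg"`, `"final"`, `"hills"`.
#' @return A `free_energy_surface`: grid axes, `free_energy` matrix
#'   (bins1 x bins2; a 1-CV log gives a single column), logical `visited`,
#'   and the scale factor used.
#' @export
reconstruct_fes <- function(log, conditions = sim_conditions(),
                            source = c("avg", "final", "hills")) {
  stopifnot(inherits(log, "hills_log"))
  source <- match.arg(source)
  if (nrow(log$hills) == 0) stop("empty hills log")
  ncv <- length(log$cv_names)
  axes <- lapply(seq_len(ncv), function(k)
    grid_centers(log$cv_ranges[[k]], log$bin_counts[k]))
  V <- switch(source,
    avg = log$bias_avg, final = log$bias_final,
    hills = {
      pts <- if (ncv == 1) matrix(axes[[1]], ncol = 1) else
        as.matrix(expand.grid(axes[[1]], axes[[2]]))
      centers <- as.matrix(log$hills[, 1 + seq_len(ncv), drop = FALSE])
      sigmas <- as.matrix(log$hills[, 1 + ncv + seq_len(ncv), drop = FALSE])
      cpp_eval_hills(centers, sigmas, log$hills$height, pts)
    })
  if (is.null(V)) stop("hills log carries no stored bias; use source = 'hills'")
  Temp <- log$temperature
  scale <- (Temp + log$delta_T) / log$delta_T
  fe <- -scale * V
  visited <- V > 1e-10
  fe[!visited] <- NA_real_
  fe <- fe - min(fe, na.rm = TRUE)
  dim(fe) <- c(log$bin_counts[1], if (ncv == 2) log$bin_counts[2] else 1L)
  dim(visited) <- dim(fe)
  structure(list(axes = axes, cv_names = log$cv_names,
                 free_energy = fe, visited = visited, scale = scale),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("Free energy surface: %s grid, %.1f%% visited, max %.3g kcal/mol\n",
              paste(vapply(x$axes, length, integer(1)), collapse = " x "),
              100 * mean(x$visited), max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' Crop a free energy surface to its visited first-CV range
#'
#' Drops leading and trailing first-CV columns with no visited bin
#' (regions the walls kept the walker out of); interior unvisited
#' columns are left for [min_free_energy_path()] to flag.
#'
#' @param fes A `free_energy_surface`.
#' @return The cropped `free_energy_surface`.
#' @export
crop_fes <- function(fes) {
  vis <- apply(fes$visited, 1, any)
  if (!any(vis)) stop("no visited bins")
  keep <- seq(min(which(vis)), max(which(vis)))
  fes$axes[[1]] <- fes$axes[[1]][keep]
  fes$free_energy <- fes$free_energy[keep, , drop = FALSE]
  fes$visited <- fes$visited[keep, , drop = FALSE]
  fes
}

#' Count completed unbinding-rebinding cycles
#'
#' Hysteresis counting on a separation CV series: a cycle is complete
#' when the series, having visited the bound region (below
#' `bound_threshold`), reaches the unbound region (above
#' `unbound_threshold`) and returns.  Repeated recrossing is the
#' convergence signature of a funnel metadynamics run.
#'
#' @param cv_series Numeric separation series.
#' @param bound_threshold,unbound_threshold Hysteresis thresholds with
#'   `bound_threshold < unbound_threshold`.
#' @return Number of completed bound -> unbound -> bound cycles.
#' @examples
#' recrossing_count(c(1, 21, 1, 21, 1), 2, 20)  # 2
#' @export
recrossing_count <- function(cv_series, bound_threshold, unbound_threshold) {
  if (bound_threshold >= unbound_threshold)
    stop("bound_threshold must be below unbound_threshold")
  phase <- "start"
  n <- 0L
  for (v in cv_series) {
    if (v <= bound_threshold) {
      if (phase == "returning") n <- n + 1L
      phase <- "bound"
    } else if (v >= unbound_threshold && phase == "bound") {
      phase <- "returning"
    }
  }
  n
}
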