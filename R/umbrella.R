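#' Umbrella window and window ladder
#'
#' An umbrella window is a harmonic bias `(k/2) (xi - center)^2` on a
#' reaction coordinate; a ladder is an ordered set of windows covering the
#' coordinate.  The published ladders are the defaults elsewhere in the
#' package: 41 separation windows of 0.5 A over 5-25 A at
#' k = 5 kcal/mol/A^2, and 7 (site) or 11 (bulk) conformational windows
#' of 0.5 A at k = 0.01.
#'
#' @param center Window centre, CV units.
#' @param k Harmonic constant, kcal/mol per (CV unit)^2 (>= 0).
#' @param cv CV label.
#' @param samples Optional sampled CV values (filled by [run_umbrella()]).
#' @return An `umbrella_window`.
#' @export
umbrella_window <- function(center, k, cv = "r", samples = NULL) {
  if (k < 0) stop("k must be non-negative")
  structure(list(cv = cv, center = center, k = k, samples = samples),
            class = "umbrella_window")
}

#' @param centers Strictly increasing window centres; alternatively give
#'   `from`, `to`, `spacing`.
#' @param from,to,spacing Arithmetic ladder specification (inclusive
#'   endpoints; the published separation ladder `from = 5, to = 25,
#'   spacing = 0.5` gives 41 windows).
#' @rdname umbrella_window
#' @export
window_ladder <- function(centers = NULL, k = 5, cv = "r",
                          from = 5, to = 25, spacing = 0.5) {
  if (is.null(centers)) centers <- seq(from, to, by = spacing)
  if (any(diff(centers) <= 0)) stop("window centres must be strictly increasing")
  structure(list(windows = lapply(centers, umbrella_window, k = k, cv = cv),
                 centers = centers, k = k, cv = cv,
                 spacing = if (length(centers) > 1) stats::median(diff(centers)) else NA),
            class = "window_ladder")
}

#' @export
print.window_ladder <- function(x, ...) {
  cat(sprintf("Umbrella ladder (%s): %d windows on [%g, %g], k = %g\n",
              x$cv, length(x$windows), min(x$centers), max(x$centers), x$k))
  invisible(x)
}

#' Harmonic umbrella bias
#'
#' @param xi CV value(s).
#' @param window An [umbrella_window()] (or any list with `center`, `k`).
#' @return `(k/2) (xi - center)^2`, kcal/mol.
#' @export
harmonic_bias <- function(xi, window) {
  0.5 * window$k * (xi - window$center)^2
}

#' Seed umbrella windows from a biased trajectory
#'
#' For every window centre, select the trajectory frame whose CV value is
#' nearest (ties broken by earliest time), the standard way of seeding a
#' separation ladder from the unbinding pathway of a metadynamics run.
#'
#' @param traj A `toy_trajectory` whose `cv_values` contain the reaction
#'   coordinate, or a plain list with `coords` and `cv_values`.
#' @param ladder A [window_ladder()].
#' @param cv Column of `cv_values` to match (name or index); default 1.
#' @return Matrix of initial coordinates, one row per window, with the
#'   selected frame index as attribute `frame`.
#' @export
seed_windows_from_path <- function(traj, ladder, cv = 1) {
  v <- traj$cv_values[, cv]
  rng <- range(v)
  out <- matrix(NA_real_, length(ladder$centers), ncol(traj$coords))
  frames <- integer(length(ladder$centers))
  for (i in seq_along(ladder$centers)) {
    ce <- ladder$centers[i]
    if (ce < rng[1] || ce > rng[2])
      stop(sprintf("window centre %g outside the trajectory CV range [%g, %g]",
                   ce, rng[1], rng[2]))
    j <- which.min(abs(v - ce))   # first index = earliest time on ties
    frames[i] <- j
    out[i, ] <- traj$coords[j, ]
  }
  attr(out, "frame") <- frames
  out
}

# umbrella CV specification: a coordinate projection or a radial distance
umbrella_cv_dim <- function(dim) list(type = "dim", dim = as.integer(dim))
umbrella_cv_radial <- function(dims, center = NULL) {
  list(type = "radial", dims = as.integer(dims),
       center = if (is.null(center)) rep(0, length(dims)) else center)
}

ucv_bias_term <- function(ucv, center, k) {
  if (ucv$type == "dim")
    list(type = "harmonic", dims = ucv$dim, a = k, c = center)
  else
    list(type = "radial_harmonic", dims = ucv$dims, center = ucv$center,
         a = k, c = center)
}

ucv_values <- function(ucv, coords) {
  if (ucv$type == "dim") return(coords[, ucv$dim])
  d <- sweep(coords[, ucv$dims, drop = FALSE], 2, ucv$center)
  sqrt(rowSums(d^2))
}

#' Run an umbrella-sampling ladder on a toy potential
#'
#' Independent seeded Langevin runs per window under the potential plus
#' the window's harmonic bias (plus any extra restraints), discarding a
#' burn-in fraction (default the first half, matching the published
#' protocol of keeping the last half of each window).
#'
#' @param potential A [toy_potential()].
#' @param ucv Umbrella CV: either a coordinate index, or the result of
#'   `umbrella_cv_radial(dims, center)` for a radial-distance CV.
#' @param ladder A [window_ladder()].
#' @param params A [langevin_params()]; `params$seed` seeds the whole
#'   ladder deterministically.
#' @param conditions A [sim_conditions()].
#' @param extra_restraints Optional list of additional potential terms
#'   active in every window (e.g. conformational and angular restraints
#'   during the separation stage).
#' @param x0_frames Optional matrix of initial coordinates per window
#'   (from [seed_windows_from_path()]); by default each window starts at
#'   its own centre along the CV.
#' @param burn_in Fraction of each window discarded.
#' @return The ladder with `samples` filled in each window (and
#'   `n_total`, `sim_length` bookkeeping).
#' @export
run_umbrella <- function(potential, ucv, ladder, params,
                         conditions = sim_conditions(),
                         extra_restraints = NULL, x0_frames = NULL,
                         burn_in = 0.5) {
  if (is.numeric(ucv) && length(ucv) == 1) ucv <- umbrella_cv_dim(ucv)
  kT <- conditions$boltzmann_constant * conditions$temperature
  nw <- length(ladder$windows)
  with_seed(params$seed, {
    for (i in seq_len(nw)) {
      w <- ladder$windows[[i]]
      bias <- c(list(ucv_bias_term(ucv, w$center, w$k)), extra_restraints)
      if (!is.null(x0_frames)) {
        x0 <- x0_frames[i, ]
      } else {
        lo <- ifelse(is.finite(potential$domain_lower), potential$domain_lower, -1)
        hi <- ifelse(is.finite(potential$domain_upper), potential$domain_upper, 1)
        x0 <- (lo + hi) / 2
        if (ucv$type == "dim") {
          x0[ucv$dim] <- w$center
        } else {
          x0[ucv$dims] <- ucv$center
          x0[ucv$dims[1]] <- ucv$center[1] + w$center
        }
      }
      res <- cpp_langevin(c(potential$terms, bias), as.numeric(x0),
                          params$timestep, params$friction, params$n_steps,
                          params$save_stride, kT, potential$domain_lower,
                          potential$domain_upper, 10, pot_wrap(potential))
      v <- ucv_values(ucv, res$coords)
      keep <- v[seq_along(v) > burn_in * length(v)]
      if (length(keep) < 100)
        stop(sprintf("window %d has only %d post-burn-in samples", i,
                     length(keep)))
      w$samples <- keep
      w$sim_length <- params$n_steps * params$timestep
      ladder$windows[[i]] <- w
    }
  })
  ladder
}

#' Weighted histogram analysis of an umbrella ladder
#'
#' Self-consistent WHAM iteration over shared bins: the unbiased density
#' and the per-window free energy offsets `f_i` are updated until the
#' largest offset change falls below `tolerance`; the PMF is
#' `-kT log(density)`, aligned to zero at its minimum.  Initialization is
#' deterministic (`f_i = 0`), so the result depends only on the samples.
#'
#' @param ladder A [window_ladder()] with samples (from [run_umbrella()]
#'   or built by hand).
#' @param bin_count Number of shared histogram bins.
#' @param tolerance Convergence threshold on the offsets, kcal/mol.
#' @param conditions A [sim_conditions()].
#' @param range Optional RC range for the bins; defaults to the sampled
#'   range.
#' @param max_iter Iteration cap.
#' @param errors If `TRUE`, block-average standard errors from 4 blocks
#'   per window.
#' @return A `wham_result`: `pmf` ([profile1d()]), `offsets`,
#'   `iterations`, `converged`, `tolerance`, `bin_centers`, `counts`.
#' @export
wham <- function(ladder, bin_count = 200, tolerance = 1e-7,
                 conditions = sim_conditions(), range = NULL,
                 max_iter = 1e5, errors = FALSE) {
  windows <- ladder$windows
  if (length(windows) < 1) stop("need at least one window")
  for (w in windows) if (is.null(w$samples) || length(w$samples) == 0)
    stop("every window needs samples")
  kT <- conditions$boltzmann_constant * conditions$temperature
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(range)) range <- base::range(all_s)
  h <- diff(range) / bin_count
  centers <- range[1] + (seq_len(bin_count) - 0.5) * h
  counts_w <- vapply(windows, function(w) {
    idx <- floor((w$samples - range[1]) / h)
    idx <- pmax(pmin(idx, bin_count - 1), 0)
    tabulate(idx + 1, nbins = bin_count)
  }, numeric(bin_count))
  n_j <- rowSums(counts_w)
  if (length(windows) > 1) {
    ord <- order(vapply(windows, `[[`, numeric(1), "center"))
    hi_i <- vapply(windows[ord], function(w) max(w$samples), numeric(1))
    lo_i <- vapply(windows[ord], function(w) min(w$samples), numeric(1))
    if (any(hi_i[-length(hi_i)] < lo_i[-1]))
      stop("non-overlapping windows: the reaction coordinate coverage is disconnected")
  }
  N_i <- vapply(windows, function(w) length(w$samples), numeric(1))
  B <- vapply(windows, function(w) harmonic_bias(centers, w), numeric(bin_count))
  expB <- exp(-B / kT)  # bin x window
  f <- rep(0, length(windows))
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    denom <- as.numeric(expB %*% (N_i * exp(f / kT)))
    p <- ifelse(denom > 0, n_j / denom, 0)
    p <- p / sum(p)
    zi <- as.numeric(crossprod(expB, p))
    f_new <- -kT * log(zi)
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta <= tolerance) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  fe <- ifelse(p > 0, -kT * log(p / h), NA_real_)
  unc <- NULL
  if (errors) {
    block_pmf <- lapply(1:4, function(b) {
      lb <- ladder
      lb$windows <- lapply(windows, function(w) {
        n <- length(w$samples)
        sel <- seq.int(floor((b - 1) * n / 4) + 1, floor(b * n / 4))
        w$samples <- w$samples[sel]
        w
      })
      wham(lb, bin_count, tolerance * 10, conditions, range, max_iter,
           errors = FALSE)$pmf$free_energy
    })
    bm <- do.call(cbind, block_pmf)
    unc <- apply(bm, 1, stats::sd) / sqrt(4)
  }
  structure(list(
    pmf = profile1d(centers, fe, uncertainty = unc, cv_name = ladder$cv),
    offsets = f, iterations = it, converged = converged,
    tolerance = tolerance, bin_centers = centers, counts = n_j),
    class = "wham_result")
}

#' Write / read umbrella window samples as COLVAR files
#'
#' One COLVAR-dialect file per window (`window_001.colvar`, ...) with
#' the window centre and elastic constant on `#! SET` metadata lines.
#'
#' @param ladder A sampled [window_ladder()].
#' @param dir Directory for the window files.
#' @return `read_window_samples()` returns the reconstructed ladder.
#' @export
write_window_samples <- function(ladder, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ladder$windows)) {
    w <- ladder$windows[[i]]
    write_colvar(seq_along(w$samples), w$samples, ladder$cv,
                 file.path(dir, sprintf("window_%03d.colvar", i)),
                 meta = list(center = w$center, k = w$k))
  }
  invisible(dir)
}

#' @rdname write_window_samples
#' @export
read_window_samples <- function(dir) {
  files <- sort(list.files(dir, pattern = "^window_\\d+\\.colvar$",
                           full.names = TRUE))
  if (!length(files)) stop("no window files in ", dir)
  windows <- lapply(files, function(f) {
    r <- read_colvar(f)
    umbrella_window(center = r$meta$center, k = r$meta$k,
                    cv = names(r$data)[2], samples = r$data[[2]])
  })
  centers <- vapply(windows, `[[`, numeric(1), "center")
  lad <- window_ladder(centers = centers, k = windows[[1]]$k,
                       cv = windows[[1]]$cv)
  lad$windows <- windows
  lad
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("WHAM: %d bins, %d iterations, %sconverged (tol %g kcal/mol)\n",
              length(x$bin_centers), x$iterations,
              if (x$converged) "" else "NOT ", x$tolerance))
  invisible(x)
}
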