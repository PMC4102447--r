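#' Adaptive biasing force estimator
#'
#' Bins a 1-D reaction coordinate and accumulates the instantaneous
#' collective force `-dU/dxi` per bin.  The applied bias is minus the
#' ramped running mean, which progressively cancels the mean force so the
#' coordinate diffuses freely; the PMF follows by integrating the mean
#' force.  Defaults follow the published protocol: bin size 0.2 (CV
#' units), a single window spanning the CV range.
#'
#' @param lo,hi Binned CV range.
#' @param bin_width Bin size (default 0.2).
#' @param ramp_threshold Samples per bin before the full bias is applied.
#' @param cv CV label.
#' @return An `abf_estimator` with `bin_edges`, `bin_centers`,
#'   `force_sums`, `counts`.
#' @export
abf_estimator <- function(lo, hi, bin_width = 0.2, ramp_threshold = 200,
                          cv = "xi") {
  nb <- max(1L, as.integer(round((hi - lo) / bin_width)))
  structure(list(lo = lo, hi = hi, n_bins = nb,
                 bin_edges = seq(lo, hi, length.out = nb + 1),
                 bin_centers = lo + (seq_len(nb) - 0.5) * (hi - lo) / nb,
                 force_sums = numeric(nb), counts = numeric(nb),
                 ramp_threshold = ramp_threshold, cv = cv),
            class = "abf_estimator")
}

abf_bin <- function(est, xi) {
  b <- floor((xi - est$lo) / (est$hi - est$lo) * est$n_bins) + 1
  ifelse(b >= 1 & b <= est$n_bins, b, NA_integer_)
}

#' Accumulate a sample into an ABF estimator
#'
#' @param est An [abf_estimator()].
#' @param xi CV value(s) of the sample(s).
#' @param force Instantaneous collective force along the CV
#'   (`-dU/dxi`), same length as `xi`.
#' @return The updated estimator; out-of-range samples are counted in
#'   `n_out_of_range` but not stored.
#' @export
abf_accumulate <- function(est, xi, force) {
  stopifnot(length(xi) == length(force))
  b <- abf_bin(est, xi)
  ok <- !is.na(b)
  if (any(ok)) {
    est$force_sums <- est$force_sums +
      as.numeric(tapply_sum(force[ok], b[ok], est$n_bins))
    est$counts <- est$counts +
      as.numeric(tabulate(b[ok], nbins = est$n_bins))
  }
  est$n_out_of_range <- (est$n_out_of_range %||% 0) + sum(!ok)
  est
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Running mean force and applied bias force
#'
#' `abf_mean_force()` returns the per-bin running mean of the accumulated
#' collective force (NA for empty bins).  `abf_bias_force()` returns the
#' force the estimator applies along the CV at a value `xi`: minus the
#' ramped running mean, `-mean * min(1, count / ramp_threshold)`, zero in
#' empty bins — full cancellation of the estimated mean force once the
#' bin has passed the ramp.
#'
#' @param est An [abf_estimator()].
#' @param xi CV value(s).
#' @return Force(s) in kcal/mol per CV unit.
#' @export
abf_bias_force <- function(est, xi) {
  b <- abf_bin(est, xi)
  out <- numeric(length(xi))
  ok <- !is.na(b) & est$counts[ifelse(is.na(b), 1, b)] > 0
  bb <- b[ok]
  mean_f <- est$force_sums[bb] / est$counts[bb]
  scale <- pmin(1, est$counts[bb] / est$ramp_threshold)
  out[ok] <- -mean_f * scale
  out
}

#' @rdname abf_bias_force
#' @export
abf_mean_force <- function(est) {
  ifelse(est$counts > 0, est$force_sums / est$counts, NA_real_)
}

#' Integrate an ABF estimator into a PMF
#'
#' `PMF(xi) = -integral of the mean force` by the trapezoid rule over the
#' contiguous sampled bins, aligned to zero at its minimum.  For a
#' periodic (dihedral) CV the end-to-end closure mismatch is reported as
#' attribute `closure_error`.
#'
#' @param est An [abf_estimator()].
#' @param periodic Treat the CV as periodic and report the closure
#'   mismatch.
#' @return A [profile1d()] over the sampled bins.
#' @export
integrate_pmf <- function(est, periodic = FALSE) {
  occ <- which(est$counts > 0)
  if (length(occ) < 2) stop("fewer than two sampled bins")
  if (any(diff(occ) > 1))
    stop("gap in sampled bins: the mean force cannot be integrated across it")
  x <- est$bin_centers[occ]
  mf <- est$force_sums[occ] / est$counts[occ]
  dx <- diff(x)
  pmf <- c(0, cumsum(-dx * (mf[-1] + mf[-length(mf)]) / 2))
  out <- profile1d(x, pmf, cv_name = est$cv)
  if (periodic) {
    # with full periodic coverage the integral of the mean force vanishes
    attr(out, "closure_error") <- abs(pmf[length(pmf)] - pmf[1] +
      (est$hi - est$lo - (x[length(x)] - x[1])) * mean(mf[c(1, length(mf))]))
  }
  out
}

#' @export
print.abf_estimator <- function(x, ...) {
  cat(sprintf("ABF estimator (%s): %d bins on [%g, %g], %d samples, ramp %d\n",
              x$cv, x$n_bins, x$lo, x$hi, sum(x$counts),
              as.integer(x$ramp_threshold)))
  invisible(x)
}

#' Run adaptive biasing force sampling on a toy potential
#'
#' Langevin dynamics with on-the-fly ABF along one coordinate of the toy
#' potential (direct force projection; the CVs of the toy systems are
#' simple coordinates, so no extended-Lagrangian machinery is needed).
#'
#' @param potential A [toy_potential()].
#' @param cv_dim Coordinate index of the CV.
#' @param range Binned CV range (length 2).
#' @param params A [langevin_params()].
#' @param conditions A [sim_conditions()].
#' @param bin_width Bin size (default 0.2 as published).
#' @param ramp_threshold Per-bin ramp before full biasing.
#' @param extra_restraints Optional list of additional potential terms.
#' @param x0 Initial coordinates.
#' @return A list with `estimator` (filled [abf_estimator()]), `pmf`
#'   (from [integrate_pmf()]) and `cv_series`.
#' @export
run_abf <- function(potential, cv_dim, range, params,
                    conditions = sim_conditions(), bin_width = 0.2,
                    ramp_threshold = 200, extra_restraints = NULL,
                    x0 = NULL) {
  est <- abf_estimator(range[1], range[2], bin_width, ramp_threshold)
  if (is.null(x0)) {
    lo <- ifelse(is.finite(potential$domain_lower), potential$domain_lower, -1)
    hi <- ifelse(is.finite(potential$domain_upper), potential$domain_upper, 1)
    x0 <- (lo + hi) / 2
  }
  kT <- conditions$boltzmann_constant * conditions$temperature
  terms <- c(potential$terms, extra_restraints)
  res <- with_seed(params$seed,
    cpp_abf(terms, as.numeric(x0), params$timestep, params$friction,
            params$n_steps, params$save_stride, kT, cv_dim,
            range[1], range[2], est$n_bins, ramp_threshold,
            potential$domain_lower, potential$domain_upper, 10,
            pot_wrap(potential)))
  est$force_sums <- res$force_sums
  est$counts <- res$counts
  est$n_out_of_range <- res$n_out_of_range
  list(estimator = est, pmf = integrate_pmf(est), cv_series = res$cv_series)
}
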