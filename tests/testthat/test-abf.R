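test_that("force accumulation and ramped cancellation behave per contract", {
  est <- abf_estimator(0, 2, bin_width = 0.2, ramp_threshold = 2)
  est <- abf_accumulate(est, 0.5, 1.4)
  expect_equal(abf_mean_force(est)[3], 1.4)
  est <- abf_accumulate(est, 0.5, -1.4)
  expect_equal(abf_mean_force(est)[3], 0)
  # ramped bias: half weight after one sample, full after the threshold
  est2 <- abf_accumulate(abf_estimator(0, 2, 0.2, ramp_threshold = 2),
                         0.5, 1)
  expect_equal(abf_bias_force(est2, 0.5), -0.5)
  est2 <- abf_accumulate(est2, 0.51, 1)
  expect_equal(abf_bias_force(est2, 0.5), -1)   # full cancellation
  expect_equal(abf_bias_force(est2, 1.5), 0)    # empty bin
  est2 <- abf_accumulate(est2, 5, 1)            # out of range: logged only
  expect_equal(est2$n_out_of_range, 1)
  expect_equal(sum(est2$counts), 2)
})

test_that("mean-force integration reproduces closed forms", {
  # constant force f over length L -> linear PMF of range |f| L
  est <- abf_estimator(0, 1, bin_width = 0.1)
  est <- abf_accumulate(est, seq(0.05, 0.95, 0.1), rep(-2, 10))
  pmf <- integrate_pmf(est)
  expect_equal(diff(range(pmf$free_energy)), 2 * 0.9, tolerance = 1e-9)
  # gap detection
  gap <- abf_accumulate(abf_estimator(0, 1, 0.1), c(0.05, 0.55), c(1, 1))
  expect_error(integrate_pmf(gap), "gap")
})

test_that("sampled mean forces match the analytic derivative of a well", {
  pot <- harmonic_1d(k = 3, center = 5)
  res <- run_abf(pot, 1L, c(3.4, 6.6),
                 langevin_params(n_steps = 4e5, seed = 14, save_stride = 20),
                 cond310, bin_width = 0.2, x0 = 5)
  mf <- abf_mean_force(res$estimator)
  centers <- res$estimator$bin_centers
  sel <- res$estimator$counts > 500
  se <- sqrt(cond310$kT * 3 / pmax(res$estimator$counts, 1))  # crude scale
  expect_true(all(abs(mf[sel] - (-3 * (centers[sel] - 5))) <
                    pmax(3 * se[sel], 0.35)))
  # integrated PMF matches (k/2)(x - 5)^2 within 0.1 kcal/mol
  ref <- 1.5 * (res$pmf$rc - 5)^2
  expect_lt(rms_vs_reference(res$pmf$rc, res$pmf$free_energy, ref), 0.1)
})

test_that("ABF flattens occupancy on a barriered potential", {
  dw <- make_double_well(barrier = 6, center = 0, halfspan = 1.5)
  res <- run_abf(dw, 1L, c(-2.2, 2.2),
                 langevin_params(n_steps = 1.2e6, seed = 15, save_stride = 5),
                 cond310, bin_width = 0.2, x0 = -1.5)
  v <- res$cv_series
  n <- length(v)
  occ <- function(x) hist(x[x > -2 & x < 2], breaks = seq(-2, 2, 0.4),
                          plot = FALSE)$counts
  cv_first <- stats::sd(occ(v[1:(n %/% 4)])) / mean(occ(v[1:(n %/% 4)]))
  lastq <- v[(3 * n %/% 4):n]
  cv_last <- stats::sd(occ(lastq)) / mean(occ(lastq))
  expect_lt(cv_last, cv_first)
  o <- occ(lastq)
  expect_lt(max(o) / min(o), 3)   # free-diffusion-like occupancy
})

test_that("a periodic dihedral CV integrates with small closure mismatch", {
  pot <- toy_potential(
    1, list(list(type = "gaussian", dims = 1L, a = 3, center = 0,
                 sigma = 35)),
    domain_lower = -180, domain_upper = 180,
    periodic = list(dims = 1L, lo = -180, hi = 180))
  res <- run_abf(pot, 1L, c(-180, 180),
                 langevin_params(timestep = 0.002, friction = 0.05,
                                 n_steps = 2e6, seed = 16, save_stride = 50),
                 cond310, bin_width = 4, x0 = 100)
  pmf <- integrate_pmf(res$estimator, periodic = TRUE)
  expect_lt(attr(pmf, "closure_error"), 0.2)
  ref <- 3 * exp(-pmf$rc^2 / (2 * 35^2))
  expect_lt(rms_vs_reference(pmf$rc, pmf$free_energy, ref), 0.15)
})

test_that("estimator state round-trips through its text format", {
  est <- abf_accumulate(abf_estimator(0, 2, 0.2, ramp_threshold = 50,
                                      cv = "theta"),
                        c(0.3, 0.31, 1.1), c(1, 2, -0.5))
  path <- tempfile()
  write_abf_state(est, path)
  back <- read_abf_state(path)
  expect_equal(back$counts, est$counts)
  expect_equal(back$force_sums, est$force_sums, tolerance = 1e-12)
  expect_equal(back$bin_centers, est$bin_centers)
  expect_equal(back$cv, "theta")
})
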