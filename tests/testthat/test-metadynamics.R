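test_that("well-tempered hill heights follow the exponential schedule", {
  s <- wt_schedule()   # omega 1, delta_T 3100
  expect_equal(wt_hill_height(0, s, cond310), 1)
  expect_equal(wt_hill_height(1, s, cond310),
               exp(-1 / (0.0019872041 * 3100)), tolerance = 1e-12)
  expect_equal(wt_hill_height(1, s, cond310), 0.850, tolerance = 1e-3)
  expect_lt(wt_hill_height(500, s, cond310), 1e-30)
  v <- wt_hill_height(seq(0, 10, 0.5), s, cond310)
  expect_true(all(diff(v) < 0))
  expect_error(wt_hill_height(-0.1, s, cond310), "non-negative")
  # bias-factor specification: delta_T = bias_factor * T
  s2 <- wt_schedule(delta_T = NULL, bias_factor = 10)
  expect_equal(wt_hill_height(1, s2, cond310), wt_hill_height(1, s, cond310))
})

test_that("bias evaluation sums Gaussian hills", {
  log <- structure(list(
    schedule = wt_schedule(sigmas = c(0.4, 0.05)),
    hills = data.frame(time = 1, center_a = 5, center_b = 2,
                       sigma_a = 0.4, sigma_b = 0.05, height = 0.8),
    cv_names = c("a", "b"), cv_ranges = list(c(0, 24), c(0, 6)),
    bin_counts = c(400L, 350L), delta_T = 3100, temperature = 310),
    class = "hills_log")
  empty <- log; empty$hills <- log$hills[0, ]
  expect_equal(bias_value(c(5, 2), empty), 0)
  expect_equal(bias_value(c(5, 2), log), 0.8)
  expect_equal(bias_value(c(5.4, 2), log), 0.8 * exp(-0.5))
  expect_equal(bias_value(c(5, 2.05), log), 0.8 * exp(-0.5))
})

test_that("a single hill reconstructs to a scaled inverted Gaussian", {
  log <- structure(list(
    schedule = wt_schedule(sigmas = 0.4),
    hills = data.frame(time = 1, center_x = 12, sigma_x = 0.4, height = 0.9),
    cv_names = "x", cv_ranges = list(c(4, 20)), bin_counts = 320L,
    delta_T = 3100, temperature = 310), class = "hills_log")
  fes <- reconstruct_fes(log, cond310, source = "hills")
  expect_equal(fes$scale, (310 + 3100) / 3100)  # 1.1
  fe <- fes$free_energy[fes$visited]
  expect_equal(min(fe), 0)
  # tolerance covers the half-bin offset of the grid from the hill centre
  expect_equal(max(fe) - min(fe), 1.1 * 0.9, tolerance = 5e-3)
  log0 <- log
  log0$hills <- log$hills[0, ]
  expect_error(reconstruct_fes(log0, cond310), "empty")
})

test_that("funnel wall energy is one-sided harmonic in the radial excess", {
  f <- funnel_spec(radius = 15, wall_constant = 100)
  expect_equal(funnel_wall_energy(c(3, 0, 0), f), 0)
  expect_equal(funnel_wall_energy(c(3, 15, 0), f), 0)
  expect_equal(funnel_wall_energy(c(3, 16, 0), f), 50)
  expect_equal(funnel_wall_energy(c(3, 0, 20), f), 0.5 * 100 * 25)
  expect_error(funnel_spec(radius = -2), "positive")
})

test_that("recrossing counting uses hysteresis thresholds", {
  expect_equal(recrossing_count(c(1, 21, 1, 21, 1), 2, 20), 2)
  expect_equal(recrossing_count(seq(0, 24, 0.5), 2, 20), 0)
  expect_equal(recrossing_count(c(1, 15, 1, 15, 1), 2, 20), 0)
  expect_equal(recrossing_count(c(21, 1, 21, 1), 2, 20), 1)
  expect_error(recrossing_count(1:10, 20, 2), "below")
})

test_that("the infinite-boost limit is standard metadynamics", {
  dw <- make_double_well()
  run <- run_metad(dw, metad_cv("x", 1L, c(4, 20), 160),
                   wt_schedule(delta_T = Inf, sigmas = 0.4),
                   langevin_params(n_steps = 2e4, seed = 2, save_stride = 50),
                   cond310, x0 = 8)
  expect_true(all(abs(run$hills_log$hills$height - 1) < 1e-12))
})

test_that("hill heights decay as bias accumulates in a visited well", {
  dw <- make_double_well()
  run <- run_metad(dw, metad_cv("x", 1L, c(4, 20), 320),
                   wt_schedule(sigmas = 0.4),
                   langevin_params(n_steps = 2e5, seed = 3, save_stride = 100),
                   cond310, x0 = 8)
  h <- run$hills_log$hills$height
  expect_lt(mean(tail(h, 100)), mean(head(h, 100)))
  expect_true(all(h > 0 & h <= 1))
})

test_that("a tight funnel confines the transverse excursion statistics", {
  pot <- toy_potential(3, list(list(type = "harmonic", dims = 1L, a = 0.5,
                                    c = 5)),
                       domain_lower = rep(-30, 3), domain_upper = rep(30, 3))
  f <- funnel_spec(radius = 2, wall_constant = 100, origin = c(0, 0, 0))
  run <- run_metad(pot, metad_cv("x", 1L, c(0, 10), 100),
                   wt_schedule(sigmas = 0.4),
                   langevin_params(n_steps = 2e5, seed = 8, save_stride = 10),
                   cond310, funnel = f, x0 = c(5, 0, 0))
  rho <- sqrt(rowSums(run$trajectory$coords[, 2:3]^2))
  sigma_wall <- sqrt(cond310$kT / 100)
  expect_lt(mean(rho > 2 + 3 * sigma_wall), 0.003)
  expect_lt(max(rho), 2 + 6 * sigma_wall)
})

test_that("hills logs round-trip through the HILLS text format", {
  dw <- make_double_well()
  run <- run_metad(dw, metad_cv("x", 1L, c(4, 20), 160),
                   wt_schedule(sigmas = 0.4),
                   langevin_params(n_steps = 1e4, seed = 4, save_stride = 100),
                   cond310, x0 = 8)
  path <- tempfile(fileext = ".hills")
  write_hills(run$hills_log, path)
  back <- read_hills(path)
  expect_equal(back$hills$time, run$hills_log$hills$time)
  expect_equal(back$hills$height, run$hills_log$hills$height)
  expect_equal(back$cv_ranges, run$hills_log$cv_ranges)
  expect_equal(back$bin_counts, run$hills_log$bin_counts,
               ignore_attr = TRUE)
  # FES rebuilt from the file matches the stored-grid FES
  f1 <- reconstruct_fes(run$hills_log, cond310, source = "final")
  f2 <- reconstruct_fes(back, cond310, source = "hills")
  ok <- f1$visited & f2$visited
  expect_lt(max(abs(f1$free_energy[ok] - f2$free_energy[ok])), 0.02)
})
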