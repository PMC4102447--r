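test_that("harmonic window bias has the textbook form", {
  w <- umbrella_window(center = 10, k = 5)
  expect_equal(harmonic_bias(10, w), 0)
  expect_equal(harmonic_bias(10.5, w), 0.625)
  expect_equal(harmonic_bias(9.3, w), harmonic_bias(10.7, w))
  expect_error(umbrella_window(0, k = -1), "non-negative")
})

test_that("the published separation ladder has 41 inclusive windows", {
  lad <- window_ladder()   # 5..25 by 0.5 at k = 5
  expect_equal(length(lad$windows), 41)
  expect_equal(lad$centers[1], 5)
  expect_equal(lad$centers[41], 25)
  expect_error(window_ladder(centers = c(1, 1, 2)), "increasing")
})

test_that("window seeding picks nearest frames with earliest-time ties", {
  traj <- list(coords = matrix(c(0, 1, 2, 3, 2, 5), ncol = 1),
               cv_values = matrix(c(0, 1, 2, 3, 2, 5), ncol = 1))
  lad <- window_ladder(centers = c(1, 2, 2.5, 4), k = 1, cv = "x")
  seeds <- seed_windows_from_path(traj, lad)
  # 2.5 is equidistant from frames 3 and 5 (values 2 and 3): earliest wins;
  # 4 is equidistant from values 3 and 5: frame 4 precedes frame 6
  expect_equal(attr(seeds, "frame"), c(2, 3, 3, 4))
  expect_equal(seeds[, 1], c(1, 2, 2, 3))
  bad <- window_ladder(centers = 9, k = 1)
  expect_error(seed_windows_from_path(traj, bad), "outside")

  dw <- make_double_well()
  run <- run_metad(dw, metad_cv("x", 1L, c(4, 20), 160),
                   wt_schedule(sigmas = 0.4),
                   langevin_params(n_steps = 2e5, seed = 6, save_stride = 20),
                   cond310, x0 = 8)
  lad41 <- window_ladder(from = 6, to = 18, spacing = 0.3, k = 5)
  seeds <- seed_windows_from_path(run$trajectory, lad41)
  expect_equal(nrow(seeds), length(lad41$centers))
})

test_that("flat-potential windows have Gaussian statistics and overlap", {
  pot <- flat_1d(0, 10)
  lad <- window_ladder(from = 3, to = 7, spacing = 0.5, k = 5, cv = "x")
  lad <- run_umbrella(pot, 1L, lad,
                      langevin_params(n_steps = 2e5, seed = 9,
                                      save_stride = 5), cond310)
  v <- vapply(lad$windows, function(w) var(w$samples), numeric(1))
  expect_equal(mean(v), cond310$kT / 5, tolerance = 0.1)
  # neighbouring-window histogram overlap above 5%
  br <- seq(0, 10, 0.1)
  for (i in seq_len(length(lad$windows) - 1)) {
    h1 <- hist(lad$windows[[i]]$samples, breaks = br, plot = FALSE)$density
    h2 <- hist(lad$windows[[i + 1]]$samples, breaks = br, plot = FALSE)$density
    expect_gt(sum(pmin(h1, h2)) * 0.1, 0.05)
  }
  again <- run_umbrella(pot, 1L, window_ladder(from = 3, to = 7,
                                               spacing = 0.5, k = 5,
                                               cv = "x"),
                        langevin_params(n_steps = 2e5, seed = 9,
                                        save_stride = 5), cond310)
  expect_identical(vapply(again$windows, function(w) w$samples[1], 1),
                   vapply(lad$windows, function(w) w$samples[1], 1))
  expect_error(
    run_umbrella(pot, 1L, window_ladder(centers = 5, k = 5, cv = "x"),
                 langevin_params(n_steps = 150, seed = 1, save_stride = 1),
                 cond310),
    "post-burn-in")
})

test_that("single-window zero-bias WHAM equals direct Boltzmann inversion", {
  set.seed(13)
  samples <- rnorm(5000, 5, 1)
  lad <- window_ladder(centers = 5, k = 0, cv = "x")
  lad$windows[[1]]$samples <- samples
  wr <- wham(lad, bin_count = 40, conditions = cond310, range = c(1, 9))
  h <- hist(samples, breaks = seq(1, 9, 0.2), plot = FALSE)$counts
  direct <- -cond310$kT * log(h)
  direct <- direct - min(direct[is.finite(direct)])
  fe <- wr$pmf$free_energy
  ok <- is.finite(fe) & is.finite(direct)
  expect_equal(fe[ok], direct[ok], tolerance = 1e-10)
  expect_true(wr$converged)
})

test_that("WHAM recovers a flat potential within 0.1 kcal/mol", {
  pot <- flat_1d(0, 10)
  lad <- window_ladder(from = 2, to = 8, spacing = 0.5, k = 5, cv = "x")
  lad <- run_umbrella(pot, 1L, lad,
                      langevin_params(n_steps = 5e5, seed = 10,
                                      save_stride = 5), cond310)
  wr <- wham(lad, bin_count = 60, conditions = cond310, range = c(2, 8))
  fe <- wr$pmf$free_energy
  inside <- wr$pmf$rc >= 2.5 & wr$pmf$rc <= 7.5 & is.finite(fe)
  expect_lt(diff(range(fe[inside])), 0.1)
})

test_that("WHAM is invariant to window order and flags disconnected ladders", {
  pot <- make_double_well()
  lad <- window_ladder(from = 7, to = 17, spacing = 1, k = 5, cv = "x")
  lad <- run_umbrella(pot, 1L, lad,
                      langevin_params(n_steps = 1e5, seed = 12,
                                      save_stride = 5), cond310)
  wr1 <- wham(lad, bin_count = 120, conditions = cond310, range = c(6, 18))
  perm <- lad
  perm$windows <- perm$windows[sample(seq_along(perm$windows))]
  wr2 <- wham(perm, bin_count = 120, conditions = cond310, range = c(6, 18))
  expect_equal(wr1$pmf$free_energy, wr2$pmf$free_energy, tolerance = 1e-6)

  gap <- lad
  gap$windows <- gap$windows[c(1, 2, 10, 11)]
  expect_error(wham(gap, 120, conditions = cond310), "non-overlapping")
})

test_that("pmf_depth measures bulk level minus site minimum", {
  flat <- profile1d(0:20, rep(2, 21))
  expect_equal(pmf_depth(flat, c(0, 5), c(15, 20)), 0)
  well <- profile1d(seq(0, 20, 0.1),
                    ifelse(abs(seq(0, 20, 0.1) - 3) < 1, -10, 0))
  expect_equal(pmf_depth(well, c(0, 5), c(15, 20)), 10)
  expect_error(pmf_depth(well, c(30, 40), c(15, 20)), "site")
})

test_that("window samples round-trip through per-window COLVAR files", {
  lad <- window_ladder(centers = c(1, 2), k = 3, cv = "q")
  lad$windows[[1]]$samples <- c(0.9, 1.1, 1.05)
  lad$windows[[2]]$samples <- c(2.2, 1.8)
  dir <- tempfile()
  write_window_samples(lad, dir)
  back <- read_window_samples(dir)
  expect_equal(back$centers, lad$centers)
  expect_identical(back$windows[[1]]$samples, lad$windows[[1]]$samples)
  expect_identical(back$windows[[2]]$samples, lad$windows[[2]]$samples)
  expect_equal(back$windows[[2]]$k, 3)
})
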