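test_that("simulation conditions satisfy their defining identities", {
  cond <- sim_conditions()
  expect_equal(cond$beta * cond$boltzmann_constant * cond$temperature, 1)
  expect_equal(cond$standard_volume, 1661)
  expect_equal(cond$kT, 0.0019872041 * 310)
  expect_error(sim_conditions(temperature = -5), "positive")
})

test_that("binding landscapes have the constructed topology", {
  cgrid <- seq(-2, 8, by = 0.02)
  rgrid <- seq(0, 25, by = 0.05)

  flat <- make_binding_landscape("flat", depth = 5)
  prof <- vapply(rgrid, function(r)
    min(potential_energy(flat, cbind(r, cgrid))), numeric(1))
  expect_equal(min(prof), -5, tolerance = 1e-12)
  # monotone non-decreasing up to the plateau, and exactly flat bulk
  expect_true(all(diff(prof[rgrid <= 15]) >= -1e-9))
  expect_lt(max(abs(prof[rgrid > 15 & rgrid <= 24])), 0.01)

  barr <- make_binding_landscape("barrier", depth = 5, barrier_height = 12)
  prof <- vapply(rgrid, function(r)
    min(potential_energy(barr, cbind(r, cgrid))), numeric(1))
  expect_equal(max(prof) - min(prof), 12, tolerance = 1e-6)
  expect_equal(rgrid[which.max(prof)], 6, tolerance = 0.1)
  expect_lt(max(abs(prof[rgrid > 15 & rgrid <= 24])), 0.01)

  expect_error(make_binding_landscape("flat", depth = -1), "positive")
  expect_error(make_binding_landscape("sideways"), "arg")
})

test_that("analytic gradients match central differences for every term family", {
  set.seed(4)
  for (pot in list(make_binding_landscape("barrier"),
                   make_binding_landscape("flat"),
                   make_double_well(),
                   make_funnel_system("barrier"),
                   make_ray_system())) {
    expect_lt(check_gradient(pot, n = 100), 1e-5)
  }
})

test_that("anchor frames realize the 5 A fictitious-point geometry", {
  frames <- make_anchor_trajectory(4, noise = 0)
  cvs <- t(vapply(frames, anchor_cvs, numeric(6)))
  expect_true(all(abs(cvs[, "r"] - 5) < 1e-12))
  expect_true(all(apply(cvs, 2, function(col) diff(range(col)) < 1e-12)))

  a <- make_anchor_trajectory(3, noise = 0.1, seed = 1)
  b <- make_anchor_trajectory(3, noise = 0.1, seed = 1)
  c2 <- make_anchor_trajectory(3, noise = 0.1, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c2))
  expect_error(make_anchor_trajectory(0), "at least 1")
})

test_that("generated path frames reproduce the prescribed MSD ladder", {
  ref <- make_path_frames(P = 7, spacing = 1)
  cons <- vapply(1:6, function(i) msd(ref$frames[[i]], ref$frames[[i + 1]]),
                 numeric(1))
  expect_equal(cons, rep(1, 6), tolerance = 1e-9)
  # linear path: MSD grows quadratically with index distance
  expect_equal(msd(ref$frames[[1]], ref$frames[[7]]), 36, tolerance = 1e-9)
  expect_equal(msd(ref$frames[[3]], ref$frames[[3]]), 0)

  two <- make_path_frames(P = 2, spacing = 0.5)
  expect_equal(msd(two$frames[[1]], two$frames[[2]]), 0.5, tolerance = 1e-9)

  a <- matrix(1:12, 4)
  expect_error(make_path_frames(P = 5, closed = a, open = a), "degenerate")
  expect_error(make_path_frames(P = 1), "at least 2")
})
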