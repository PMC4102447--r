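test_that("overdamped sampling satisfies equipartition on a harmonic well", {
  pot <- harmonic_1d(k = 2)
  tr <- langevin_sample(pot, langevin_params(n_steps = 4e5, seed = 11,
                                             save_stride = 5), cond310,
                        x0 = 0)
  expect_equal(var(tr$coords[, 1]), cond310$kT / 2, tolerance = 0.05)
})

test_that("zero temperature reduces the update to energy descent", {
  pot <- make_double_well()
  tr <- langevin_sample(pot, langevin_params(n_steps = 2000, seed = 1,
                                             save_stride = 10),
                        sim_conditions(temperature = 1e-12), x0 = 10)
  e <- potential_energy(pot, tr$coords)
  expect_true(all(diff(e) <= 1e-8))
})

test_that("trajectories are seed-reproducible with the declared frame layout", {
  pot <- make_double_well()
  pp <- langevin_params(n_steps = 1234, seed = 42, save_stride = 7)
  a <- langevin_sample(pot, pp, cond310, x0 = 8)
  b <- langevin_sample(pot, pp, cond310, x0 = 8)
  expect_identical(a$coords, b$coords)
  expect_equal(nrow(a$coords), 1234 %/% 7 + 1)
  expect_true(all(diff(a$times) > 0))
  pp$seed <- 43L
  expect_false(identical(langevin_sample(pot, pp, cond310, x0 = 8)$coords,
                         a$coords))
})

test_that("runaway coordinates signal divergence", {
  unstable <- toy_potential(1, list(list(type = "harmonic", dims = 1L,
                                         a = -2, c = 0)),
                            domain_lower = -1, domain_upper = 1)
  expect_error(
    langevin_sample(unstable, langevin_params(n_steps = 5e4, seed = 1),
                    cond310, x0 = 0.1),
    "diverged")
})

test_that("long runs reproduce the Boltzmann distribution of a double well", {
  pot <- make_double_well(barrier = 2, center = 0, halfspan = 1)
  tr <- langevin_sample(pot, langevin_params(n_steps = 1e6, seed = 5,
                                             save_stride = 2), cond310,
                        x0 = 1)
  width <- 0.1
  centers <- seq(-2.2, 2.2, by = width)
  h <- vapply(centers, function(ce)
    sum(tr$coords[, 1] >= ce - width / 2 & tr$coords[, 1] < ce + width / 2),
    numeric(1))
  p <- h / sum(h)
  q <- boltzmann_density(pot, centers, width)
  q <- q / sum(q)
  expect_lt(0.5 * sum(abs(p - q)), 0.05)   # total-variation distance
})
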