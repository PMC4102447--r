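test_that("restraint free energies from PMFs match closed forms", {
  L <- 10
  x <- seq(0, L, length.out = 4001)
  flat <- profile1d(x, rep(0, length(x)))
  expect_equal(restraint_dg_from_pmf(flat, 5, 0, cond310), 0)
  # flat PMF + harmonic restraint: Gaussian integral over length L
  k <- 6
  expected <- -cond310$kT * log(sqrt(2 * pi * cond310$kT / k) / L)
  expect_equal(restraint_dg_from_pmf(flat, 5, k, cond310), expected,
               tolerance = 1e-4)
  expect_gt(expected, 0)
  # a restraint centred on a narrow deep minimum costs almost nothing
  deep <- profile1d(x, 40 * (x - 5)^2)
  expect_lt(restraint_dg_from_pmf(deep, 5, 2, cond310), 0.02)
  # gauge invariance under additive shifts
  shifted <- profile1d(x, rep(7.3, length(x)), align = FALSE)
  expect_equal(restraint_dg_from_pmf(shifted, 5, k, cond310), expected,
               tolerance = 1e-4)
  # truncated support is flagged
  expect_error(restraint_dg_from_pmf(flat, 5, 0.001, cond310), "boundary")
})

test_that("bulk orientational term integrates the isotropic measure", {
  zero <- list(center = 0, k = 0)
  expect_equal(bulk_orientation_dg(zero, zero, zero, cond310), 0)
  # separable limit: product of three 1-D factors at 10-degree width
  kk <- cond310$kT / 10^2   # Gaussian width 10 degrees
  r10 <- list(center = 90, k = kk)
  d10a <- list(center = 0, k = kk)
  v <- bulk_orientation_dg(r10, d10a, d10a, cond310)
  f_alpha <- integrate(function(a) exp(-cond310$beta * kk / 2 * (a - 90)^2) *
                         sin(a * pi / 180), 0, 180)$value /
    integrate(function(a) sin(a * pi / 180), 0, 180)$value
  f_dih <- integrate(function(a) exp(-cond310$beta * kk / 2 * a^2),
                     -180, 180)$value / 360
  expect_equal(v, -cond310$kT * (log(f_alpha) + 2 * log(f_dih)),
               tolerance = 0.01)
  # monotone in each force constant
  stiffer <- list(center = 90, k = 4 * kk)
  expect_gt(bulk_orientation_dg(stiffer, d10a, d10a, cond310), v)
})

test_that("S* interpolates between the full sphere and the Laplace limit", {
  zero_t <- list(center = 90, k = 0)
  zero_T <- list(center = 0, k = 0)
  expect_equal(s_star(zero_t, zero_T, 10, cond310), 4 * pi * 100,
               tolerance = 1e-4)
  # stiff restraints: r*^2 sin(theta0) 2 pi kT / sqrt(k_theta k_Theta)
  kdeg <- 0.5   # kcal/mol/deg^2, very stiff
  krad <- kdeg * (180 / pi)^2
  stiff <- s_star(list(center = 60, k = kdeg), list(center = 0, k = kdeg),
                  10, cond310, n = 20001)
  laplace <- 100 * sin(60 * pi / 180) * 2 * pi * cond310$kT / krad
  expect_equal(stiff, laplace, tolerance = 0.01)
  expect_lt(s_star(list(center = 90, k = 0.04), zero_T, 10, cond310),
            s_star(list(center = 90, k = 0.02), zero_T, 10, cond310))
  expect_error(s_star(zero_t, zero_T, -1), "positive")
})

test_that("I* integrates the referenced separation Boltzmann factor", {
  x <- seq(0, 20, by = 0.002)
  flat <- profile1d(x, rep(1, length(x)), align = FALSE)
  expect_equal(i_star(flat, c(2, 7), cond310), 5, tolerance = 1e-4)
  # square well of the published wild-type depth over 1 A
  wsq <- ifelse(x >= 5 & x <= 6, -24.96, 0)
  sq <- profile1d(x, wsq, align = FALSE)
  expect_equal(i_star(sq, c(4, 8), cond310), exp(24.96 / 0.616033),
               tolerance = 0.02)
  expect_equal(log10(i_star(sq, c(4, 8), cond310)), log10(3.9e17),
               tolerance = 0.01)
  # deeper wells give larger I*, and sloped "plateaus" are rejected
  deeper <- profile1d(x, ifelse(x >= 5 & x <= 6, -26, 0), align = FALSE)
  expect_gt(i_star(deeper, c(4, 8), cond310), i_star(sq, c(4, 8), cond310))
  sloped <- profile1d(x, 0.2 * x, align = FALSE)
  expect_error(i_star(sloped, c(2, 7), cond310), "plateau")
  # point reference at r*
  expect_equal(i_star(flat, c(2, 7), cond310, r_star = 15), 5,
               tolerance = 1e-4)
})

test_that("K_bind and the standard-state free energy reproduce the published table", {
  tab <- ros1_table1()
  g <- function(cmp, col) tab[[col]][tab$component == cmp]
  for (col in c("wt", "g2032r")) {
    comps <- list(dgc_site = g("dgc_site", col), dgc_bulk = g("dgc_bulk", col),
                  dgo_alpha = g("dgo_alpha", col), dgo_beta = g("dgo_beta", col),
                  dgo_gamma = g("dgo_gamma", col), dgo_bulk = g("dgo_bulk", col),
                  dgt_theta = g("dgt_theta", col),
                  dgt_Theta = g("dgt_Theta", col),
                  s_star = g("s_star", col), i_star = g("i_star", col))
    kb <- k_bind(comps, cond310)
    expect_equal(kb, g("k_bind", col), tolerance = 0.02)
    expect_equal(dg_bind_us(kb, cond310), g("dg_bind_us", col),
                 tolerance = 0.0015)
    # zero restraints collapse the decomposition to S* I*
    z <- comps
    z[c("dgc_site", "dgc_bulk", "dgo_alpha", "dgo_beta", "dgo_gamma",
        "dgo_bulk", "dgt_theta", "dgt_Theta")] <- 0
    expect_equal(k_bind(z, cond310), comps$s_star * comps$i_star)
  }
  expect_error(k_bind(list(dgc_site = 1), cond310), "missing")
  expect_equal(dg_bind_us(1661, cond310), 0)
  expect_error(dg_bind_us(-1, cond310), "positive")
})

test_that("the funnel correction references the disk to the standard state", {
  x <- seq(0, 24, 0.1)
  prof <- profile1d(x, ifelse(x < 4, -6 * cos(pi * x / 8), 0), align = TRUE)
  f15 <- funnel_spec(radius = 15)
  v <- dg_bind_meta(prof, f15, c(0, 6), c(18, 24), cond310)
  expect_equal(abs(attr(v, "correction")),
               abs(cond310$kT * log(pi * 225 / 1661)), tolerance = 1e-12)
  expect_equal(abs(attr(v, "correction")), 0.526, tolerance = 1e-3)
  # flat profile: only the correction term remains
  flat <- profile1d(x, rep(0, length(x)))
  v0 <- dg_bind_meta(flat, f15, c(0, 6), c(18, 24), cond310)
  expect_equal(as.numeric(v0), attr(v0, "correction"))
})

test_that("minimum-free-energy pathway takes exact column minima", {
  fes <- list(axes = list(1:3, 1:3), cv_names = c("r", "c"),
              free_energy = rbind(c(5, 2, 7), c(1, 9, 9), c(4, 4, 3)),
              visited = matrix(TRUE, 3, 3))
  p <- min_free_energy_path(fes)
  expect_equal(p$free_energy, c(2, 1, 3) - 1)  # min-aligned
  # additive constants do not change the aligned path
  fes2 <- fes
  fes2$free_energy <- fes$free_energy + 11.7
  expect_equal(min_free_energy_path(fes2)$free_energy, p$free_energy)
  # constant-in-c surface returns any slice
  fes3 <- fes
  fes3$free_energy <- matrix(rep(c(3, 1, 2), 3), 3)
  expect_equal(min_free_energy_path(fes3)$free_energy, c(2, 0, 1))
  fes$free_energy[2, ] <- NA
  expect_error(min_free_energy_path(fes), "unvisited")
})

test_that("dissociation barriers and residence-time ratios are consistent", {
  x <- seq(0, 24, 0.1)
  mono <- profile1d(x, pmin(x, 9), align = FALSE)
  expect_equal(dg_off(mono), 9)
  barrier <- profile1d(x, ifelse(x < 2, 0, ifelse(x < 6, 12.10, 7)),
                       align = FALSE)
  expect_equal(dg_off(barrier, site_range = c(0, 2)), 12.10)
  flat <- profile1d(x, rep(3, length(x)), align = FALSE)
  expect_equal(dg_off(flat), 0)

  expect_equal(residence_time_ratio(5, 5, cond310), 1)
  r <- residence_time_ratio(12.10, 5.53, cond310)
  expect_equal(r, exp(6.57 / cond310$kT), tolerance = 1e-12)
  expect_equal(r, 4.3e4, tolerance = 0.01)
  expect_equal(r * residence_time_ratio(5.53, 12.10, cond310), 1)
})

test_that("assembly reports follow the published difference conventions", {
  res <- reproduce_table1()
  expect_true(all(res$pass))
  rep <- attr(res, "report")
  tab <- rep$table
  pick <- function(cmp, col) tab[tab$component == cmp, col]
  # restraint rows: mutant minus wild type
  expect_equal(pick("dgc_site", "difference"), 0.323 - 0.073)
  # energy rows: wild type minus mutant, as printed
  expect_equal(pick("sep_pmf", "difference"), -6.64, tolerance = 1e-9)
  expect_equal(pick("dg_bind_us", "difference"), -6.75, tolerance = 0.03)
  expect_equal(pick("dg_off", "difference"), 6.57, tolerance = 1e-9)
  expect_equal(pick("dg_bind_meta", "difference"), -4.23, tolerance = 1e-9)

  # identical systems: all differences vanish
  sysA <- as.list(stats::setNames(ros1_table1()$wt, ros1_table1()$component))
  sysA <- sysA[c(funnelbind:::report_components, "s_star", "i_star")]
  same <- build_report(sysA, sysA, cond310)
  expect_true(all(abs(stats::na.omit(same$table$difference)) < 1e-12))

  # lossless round-trip through the key-value serialization
  path <- tempfile()
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$table[[2]], rep$table[[2]])
  expect_equal(back$table[[3]], rep$table[[3]])
  expect_identical(back$labels, rep$labels)
})
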