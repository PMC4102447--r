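test_that("centre-of-mass distance handles masses, symmetry and errors", {
  expect_equal(com_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  pts <- matrix(rnorm(9), 3)
  expect_equal(com_distance(pts, pts), 0)
  # mass-weighted centroid of (1,3) at x = 0 and 4 sits at x = 3
  a <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(com_distance(a, c(3, 0, 0), masses_a = c(1, 3)), 0)
  expect_equal(com_distance(a, pts), com_distance(pts, a))
  expect_error(com_distance(matrix(numeric(0), 0, 3), pts), "non-empty")
  expect_error(com_distance(a, pts, masses_a = c(1, -1)), "positive")
  # analytic gradient against central differences
  g <- attr(com_distance(a, pts, masses_a = c(1, 3), gradient = TRUE),
            "grad_a")
  h <- 1e-6
  for (k in 1:3) {
    ap <- a; ap[1, k] <- ap[1, k] + h
    am <- a; am[1, k] <- am[1, k] - h
    num <- (com_distance(ap, pts, masses_a = c(1, 3)) -
              com_distance(am, pts, masses_a = c(1, 3))) / (2 * h)
    expect_equal(g[1, k], num, tolerance = 1e-5)
  }
})

test_that("angles and dihedrals follow the declared conventions", {
  expect_equal(angle(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), 45)
  expect_equal(angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_error(angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero-length")

  # cis = 0, trans = 180
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  # out-of-plane quarter turn, sign fixed by the convention
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)), 90)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, -1)), -90)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")

  # rigid-motion invariance
  set.seed(9)
  p <- lapply(1:4, function(i) rnorm(3))
  R <- random_rotation(); tr <- rnorm(3)
  move <- function(x) as.numeric(R %*% x + tr)
  expect_equal(angle(move(p[[1]]), move(p[[2]]), move(p[[3]])),
               angle(p[[1]], p[[2]], p[[3]]), tolerance = 1e-9)
  d1 <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
  d2 <- dihedral(move(p[[1]]), move(p[[2]]), move(p[[3]]), move(p[[4]]))
  expect_equal(abs(d1), abs(d2), tolerance = 1e-9)
  if (det(R) > 0) expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("msd and rmsd measure per-point displacement without fitting", {
  a <- matrix(0, 2, 3)
  expect_equal(msd(a, a), 0)
  b <- a; b[, 1] <- 1
  expect_equal(msd(a, b), 1)
  expect_equal(rmsd(a, b), 1)
  b2 <- a; b2[1, 1] <- 1; b2[2, 1] <- 3
  expect_equal(msd(a, b2), 5)  # (1 + 9) / 2
  expect_error(msd(a, matrix(0, 3, 3)), "mismatched")
  g <- attr(msd(a, b2, gradient = TRUE), "grad_a")
  expect_equal(g, 2 * (a - b2) / 2)
})

test_that("path progress runs on the MSD scale and is monotone on-path", {
  ref <- make_path_frames(P = 7, spacing = 1)
  s1 <- path_progress(ref$frames[[1]], ref)
  s7 <- path_progress(ref$frames[[7]], ref)
  expect_lt(abs(s1 - 0), 0.05)       # within 5% of the 1 A^2 spacing
  expect_lt(abs(s7 - 6), 0.05)
  for (i in 2:6)
    expect_lt(abs(path_progress(ref$frames[[i]], ref) - (i - 1)), 0.05)
  # dense interpolation along the generating path is strictly increasing
  disp <- ref$frames[[7]] - ref$frames[[1]]
  svals <- vapply(seq(0, 1, length.out = 41), function(t)
    path_progress(ref$frames[[1]] + t * disp, ref), numeric(1))
  expect_true(all(diff(svals) > 0))
  far <- ref$frames[[1]] + 1e4
  expect_error(path_progress(far, ref), "far from")
})

test_that("funnel radial distance is an axis-invariant perpendicular norm", {
  expect_equal(funnel_radial(c(7, 3, 4)), 5)
  expect_equal(funnel_radial(c(-2, 0, 0)), 0)
  expect_equal(funnel_radial(c(5, 3, 4), origin = c(99, 0, 0)), 5)
  expect_error(funnel_radial(c(1, 1, 1), direction = c(0, 0, 0)), "non-zero")
})

test_that("population histograms conserve counts and wrap dihedrals", {
  h <- population_histogram(rep(2.5, 40), bin_width = 1)
  expect_equal(sum(h$counts), 40)
  expect_equal(sum(h$counts > 0), 1)

  grid <- rep(seq(0.05, 0.95, by = 0.1), each = 100)
  h <- population_histogram(grid, bin_width = 0.1, normalize = TRUE)
  expect_true(all(h$counts == 100))
  expect_equal(sum(h$density) * h$bin_width, 1, tolerance = 1e-9)

  hc <- population_histogram(c(-179, 179, 178, -178), bin_width = 5,
                             circular = TRUE)
  expect_equal(sum(hc$counts > 0), 1)   # all four share the wrap bin
  expect_error(population_histogram(1:5, bin_width = 0), "positive")
  expect_error(population_histogram(numeric(0), 1), "empty")
})
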