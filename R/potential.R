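#' Analytic toy potentials
#'
#' A toy potential is a sum of analytic terms (compact-support bumps,
#' harmonics, quartic double wells, switched harmonic couplings, radial
#' variants, one-sided walls, Gaussians and a log-sin Jacobian weight) on a
#' low-dimensional coordinate space.  It stands in for the solvated
#' drug-kinase complex: cheap enough for dense quadrature, rich enough to
#' carry the features the free-energy estimators must recover (bound well,
#' unbinding barrier, induced-fit coupling, flat bulk plateau).
#'
#' @param dimension Number of coordinates.
#' @param terms List of term definitions.  Each term is a list with a
#'   `type` string, a `dims` integer vector of the coordinates it acts on,
#'   and named parameters `a`..`e`, `center`, `sigma` (see the package
#'   vignette for the catalogue of forms).
#' @param domain_lower,domain_upper Numeric vectors declaring the domain;
#'   dynamics signal divergence when a coordinate leaves the domain by
#'   more than 10 A.
#' @param info Optional named list of metadata (e.g. the landscape family
#'   and parameters used by [make_binding_landscape()]).
#' @param periodic Optional periodic coordinates: a list with `dims`,
#'   `lo`, `hi`; the samplers wrap these coordinates into their period
#'   after every step (used for dihedral-like angles).
#' @return An object of class `toy_potential`.
#' @seealso [potential_energy()], [potential_gradient()],
#'   [make_binding_landscape()]
#' @export
toy_potential <- function(dimension, terms, domain_lower = rep(-Inf, dimension),
                          domain_upper = rep(Inf, dimension), info = list(),
                          periodic = NULL) {
  stopifnot(dimension >= 1, is.list(terms))
  for (t in terms) {
    if (is.null(t$type) || is.null(t$dims))
      stop("every term needs a 'type' and a 'dims' field")
    if (any(t$dims < 1 | t$dims > dimension))
      stop("term dims outside the declared dimension")
  }
  structure(
    list(dimension = as.integer(dimension), terms = terms,
         domain_lower = rep_len(as.numeric(domain_lower), dimension),
         domain_upper = rep_len(as.numeric(domain_upper), dimension),
         info = info, periodic = periodic),
    class = "toy_potential")
}

#' Evaluate a toy potential
#'
#' @param potential A [toy_potential()].
#' @param x Either a numeric vector (one point) or a matrix with one point
#'   per row.
#' @return Energy in kcal/mol; a vector with one value per row of `x`.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "toy_potential"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != potential$dimension)
    stop("point dimension does not match the potential")
  cpp_pot_energy(potential$terms, x)
}

#' Analytic gradient of a toy potential
#'
#' @inheritParams potential_energy
#' @param x A single point (numeric vector).
#' @return Gradient vector, kcal/mol/A per coordinate.
#' @export
potential_gradient <- function(potential, x) {
  stopifnot(inherits(potential, "toy_potential"),
            length(x) == potential$dimension)
  cpp_pot_grad(potential$terms, as.numeric(x))
}

#' Check the analytic gradient against central differences
#'
#' @inheritParams potential_energy
#' @param points Matrix of test points (one per row); defaults to random
#'   points drawn inside the finite part of the domain.
#' @param n Number of random points when `points` is missing.
#' @param h Central-difference step.
#' @return The maximum relative deviation over all points and coordinates
#'   (relative to `max(|grad|, 1)` per point).
#' @export
check_gradient <- function(potential, points = NULL, n = 100, h = 1e-5) {
  if (is.null(points)) {
    lo <- ifelse(is.finite(potential$domain_lower), potential$domain_lower, -5)
    hi <- ifelse(is.finite(potential$domain_upper), potential$domain_upper, 5)
    points <- sapply(seq_len(potential$dimension), function(k)
      stats::runif(n, lo[k], hi[k]))
    if (potential$dimension == 1) points <- matrix(points, ncol = 1)
  }
  worst <- 0
  for (i in seq_len(nrow(points))) {
    x <- points[i, ]
    g <- potential_gradient(potential, x)
    for (k in seq_along(x)) {
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      num <- (potential_energy(potential, xp) -
              potential_energy(potential, xm)) / (2 * h)
      worst <- max(worst, abs(num - g[k]) / max(abs(g[k]), 1))
    }
  }
  worst
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("Toy potential: %d coordinate(s), %d term(s)\n",
              x$dimension, length(x$terms)))
  types <- vapply(x$terms, function(t) t$type, character(1))
  cat("  terms:", paste(sort(unique(types)), collapse = ", "), "\n")
  if (length(x$info)) cat("  info:", paste(names(x$info), collapse = ", "), "\n")
  invisible(x)
}

#' Build a 2-D "separation x loop conformation" binding landscape
#'
#' Constructs the toy analogue of the free energy topology seen for
#' crizotinib unbinding from a kinase: coordinate 1 is the ligand-pocket
#' separation r (A) on \[0, 25\] and coordinate 2 a loop-conformation
#' coordinate c on the mean-square-deviation scale (A^2).  The `barrier`
#' kind couples c to r through an induced-fit switch so that crossing the
#' saddle at r of about 4-8 A requires a conformational displacement (the
#' wild-type-like topology); the `flat` kind decouples c and has no
#' barrier (the mutant-like topology).  The bulk region (r > 15 A, in fact
#' r beyond the barrier support) is exactly flat.
#'
#' Well and barrier are compact-support quartic bumps, so the printed
#' `depth` and `barrier_height` are exact features of the minimized 1-D
#' profile: `min_c U = -depth` at the well and `max - min` of the profile
#' equals `barrier_height` for the barrier kind.
#'
#' @param profile_kind `"barrier"` or `"flat"`.
#' @param depth Well depth in kcal/mol (> 0), measured from the bulk
#'   plateau at zero.
#' @param barrier_height For the barrier kind: `max - min` of the
#'   c-minimized 1-D profile, kcal/mol; must exceed `depth` for a true
#'   barrier above the plateau.
#' @param r_well Separation of the bound minimum (flat kind pins the well
#'   at r = 0 so the minimized profile is monotone).
#' @param r_barrier Barrier position (barrier kind), default 6 A.
#' @param well_halfwidth,barrier_halfwidth Compact supports of the bumps.
#' @param k_conf Harmonic constant tying c to its reference path,
#'   kcal/mol/A^4 (c carries A^2 units).
#' @param c_closed,c_open Bound-state and bulk values of the conformational
#'   coordinate (A^2).
#' @param switch_range Separation interval over which the conformational
#'   reference moves from closed to open (barrier kind).
#' @return A [toy_potential()] with `dimension = 2` and the construction
#'   parameters in `$info`.
#' @examples
#' pot <- make_binding_landscape("barrier", depth = 5, barrier_height = 12)
#' r <- seq(0, 25, 0.1)
#' prof <- vapply(r, function(ri) min(potential_energy(
#'   pot, cbind(ri, seq(0, 6, 0.05)))), numeric(1))
#' max(prof) - min(prof)  # ~12
#' @export
make_binding_landscape <- function(profile_kind = c("barrier", "flat"),
                                   depth = 5, barrier_height = 12,
                                   r_well = 2, r_barrier = 6,
                                   well_halfwidth = 2, barrier_halfwidth = 2,
                                   k_conf = 2.5, c_closed = 1, c_open = 4,
                                   switch_range = c(4, 8)) {
  profile_kind <- match.arg(profile_kind)
  if (depth <= 0) stop("well depth must be positive")
  terms <- list()
  if (profile_kind == "flat") {
    # well pinned at r = 0: the c-minimized profile rises monotonically
    # from -depth to the plateau and the conformation is decoupled
    terms <- list(
      list(type = "bump", dims = 1L, a = -depth, b = 2 * well_halfwidth, c = 0),
      list(type = "harmonic", dims = 2L, a = k_conf, c = c_open))
  } else {
    if (barrier_height <= depth)
      stop("barrier_height must exceed depth for a barrier above the plateau")
    terms <- list(
      list(type = "bump", dims = 1L, a = -depth, b = well_halfwidth,
           c = r_well),
      list(type = "bump", dims = 1L, a = barrier_height - depth,
           b = barrier_halfwidth, c = r_barrier),
      list(type = "switch_harmonic", dims = c(2L, 1L), a = k_conf,
           b = c_closed, c = c_open, d = switch_range[1], e = switch_range[2]))
  }
  # confining walls at the domain edges so unbiased dynamics stay bounded
  terms <- c(terms, list(
    list(type = "lower_wall", dims = 1L, a = 20, c = 0),
    list(type = "upper_wall", dims = 1L, a = 20, c = 25)))
  toy_potential(
    dimension = 2, terms = terms,
    domain_lower = c(0, -5), domain_upper = c(25, 11),
    info = list(family = "binding_landscape", profile_kind = profile_kind,
                depth = depth,
                barrier_height = if (profile_kind == "barrier") barrier_height else NA,
                r_well = if (profile_kind == "flat") 0 else r_well,
                c_closed = if (profile_kind == "flat") c_open else c_closed,
                c_open = c_open, k_conf = k_conf))
}

#' The 1-D quartic double well used as the estimator benchmark
#'
#' `U(x) = barrier * (((x - center)/halfspan)^2 - 1)^2`: minima at
#' `center - halfspan` and `center + halfspan` at zero energy and a barrier
#' of exactly `barrier` kcal/mol between them, with quartic confinement
#' outside.  Every 1-D estimator in the package (well-tempered
#' metadynamics, umbrella sampling + WHAM, adaptive biasing force) is
#' validated against this closed form.
#'
#' @param barrier Barrier height, kcal/mol.
#' @param center Barrier-top position, A.
#' @param halfspan Distance from the barrier top to each minimum, A.
#' @return A 1-D [toy_potential()].
#' @export
make_double_well <- function(barrier = 5, center = 12, halfspan = 4) {
  toy_potential(
    dimension = 1,
    terms = list(list(type = "doublewell", dims = 1L, a = barrier,
                      c = center, b = halfspan)),
    domain_lower = center - 2.5 * halfspan,
    domain_upper = center + 2.5 * halfspan,
    info = list(family = "double_well", barrier = barrier, center = center,
                halfspan = halfspan,
                minima = c(center - halfspan, center + halfspan)))
}
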