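#' Centre-of-mass distance
#'
#' Euclidean distance between the mass-weighted centroids of two point
#' groups, the separation collective variable biased in the unbinding
#' simulations (drug heavy atoms vs binding-site heavy atoms).
#'
#' @param points_a,points_b Matrices with one 3-D point per row (a bare
#'   vector is taken as a single point).
#' @param masses_a,masses_b Optional positive masses per point; unit
#'   masses by default.
#' @param gradient If `TRUE`, attach the analytic derivative of the
#'   distance with respect to every point as attributes `grad_a`, `grad_b`.
#' @return Distance in A.
#' @examples
#' com_distance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
com_distance <- function(points_a, points_b, masses_a = NULL, masses_b = NULL,
                         gradient = FALSE) {
  a <- as_points(points_a); b <- as_points(points_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("point groups must be non-empty")
  ma <- if (is.null(masses_a)) rep(1, nrow(a)) else masses_a
  mb <- if (is.null(masses_b)) rep(1, nrow(b)) else masses_b
  if (any(ma <= 0) || any(mb <= 0)) stop("masses must be positive")
  if (sum(ma) == 0 || sum(mb) == 0) stop("zero total mass")
  ca <- colSums(a * ma) / sum(ma)
  cb <- colSums(b * mb) / sum(mb)
  d <- sqrt(sum((ca - cb)^2))
  if (!gradient) return(d)
  u <- if (d > 1e-12) (ca - cb) / d else rep(0, 3)
  res <- d
  attr(res, "grad_a") <- outer(ma / sum(ma), u)
  attr(res, "grad_b") <- outer(mb / sum(mb), -u)
  res
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 3) stop("points must be 3-dimensional")
  as.matrix(p)
}

#' Interior angle at the middle point
#'
#' The angle p1-p2-p3 in degrees, in \[0, 180\]; used for the rotational
#' and translational angle restraints (alpha, theta) of the unbinding
#' geometry.
#'
#' @param p1,p2,p3 3-D points.
#' @return Angle in degrees.
#' @examples
#' angle(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0))  # 45
#' @export
angle <- function(p1, p2, p3) {
  v1 <- as.numeric(p1) - as.numeric(p2)
  v2 <- as.numeric(p3) - as.numeric(p2)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length arm: p2 coincides with p1 or p3")
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Signed dihedral (torsion) angle
#'
#' The torsion p1-p2-p3-p4 in degrees on (-180, 180\], IUPAC sign
#' convention (cis = 0, trans = 180, positive for a clockwise rotation of
#' the far bond viewed along p2 -> p3).  Used for the loop-conformation
#' dihedral (four C-alpha positions) and the beta/gamma/Theta restraints.
#'
#' @param p1,p2,p3,p4 3-D points; consecutive points must not coincide and
#'   no three consecutive points may be collinear.
#' @return Signed torsion in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  if (sqrt(sum(b1^2)) < 1e-12 || sqrt(sum(b2^2)) < 1e-12 ||
      sqrt(sum(b3^2)) < 1e-12)
    stop("degenerate geometry: consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate geometry: three consecutive points are collinear")
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2n)
  atan2(y, x) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Mean-square and root-mean-square deviation between frames
#'
#' Per-point displacement statistics between two equally sized,
#' identically ordered point sets.  No superposition fit is applied: toy
#' frames are generated pre-aligned, a deliberate simplification relative
#' to all-atom practice (see the methods vignette).
#'
#' @param frame_a,frame_b Matrices with one point per row.
#' @param gradient If `TRUE` (msd only), attach `d msd / d frame_a`.
#' @return `msd()` in A^2, `rmsd()` in A.
#' @examples
#' a <- matrix(0, 2, 3); b <- a; b[, 1] <- c(1, 3)
#' msd(a, b)   # (1 + 9)/2 = 5
#' rmsd(a, b)  # sqrt(5)
#' @export
msd <- function(frame_a, frame_b, gradient = FALSE) {
  a <- as.matrix(frame_a); b <- as.matrix(frame_b)
  if (!all(dim(a) == dim(b))) stop("mismatched point counts between frames")
  d <- a - b
  v <- sum(d^2) / nrow(a)
  if (!gradient) return(v)
  res <- v
  attr(res, "grad_a") <- 2 * d / nrow(a)
  res
}

#' @rdname msd
#' @export
rmsd <- function(frame_a, frame_b) sqrt(msd(frame_a, frame_b))

#' Ordered reference frames for the path-progress variable
#'
#' @param frames List of point-set matrices, ordered from the bound
#'   ("closed") to the unbound ("open") conformation.
#' @param spacing Target mean-square deviation between consecutive frames
#'   (A^2); when `NULL`, the mean consecutive MSD of `frames`.
#' @param lambda Smoothing constant of the path variable (1/A^2); default
#'   `3 / spacing`, which reproduces each milestone at its own frame to
#'   within 5 percent of the spacing.
#' @return An object of class `path_reference`.
#' @export
path_reference <- function(frames, spacing = NULL, lambda = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2)
  cons <- vapply(seq_len(length(frames) - 1), function(i)
    msd(frames[[i]], frames[[i + 1]]), numeric(1))
  if (is.null(spacing)) spacing <- mean(cons)
  if (spacing <= 0) stop("spacing must be positive")
  if (any(abs(cons - spacing) > 0.2 * spacing))
    stop("consecutive-frame MSD deviates from the declared spacing by more than 20%")
  if (is.null(lambda)) lambda <- 3 / spacing
  structure(list(frames = frames, spacing = spacing, lambda = lambda),
            class = "path_reference")
}

#' Generate evenly spaced path frames between two endpoint conformations
#'
#' Linear interpolation between a "closed" and an "open" point set, scaled
#' so that the MSD between consecutive frames equals `spacing` exactly.
#' Along a linear path the MSD grows quadratically with index distance,
#' so `MSD(frame_1, frame_P) = (P - 1)^2 * spacing` (36 A^2 for the
#' default 7 frames at 1 A^2).
#'
#' @param P Number of frames (>= 2); default 7 as in the loop-conformation
#'   path of the kinase study.
#' @param spacing Consecutive-frame MSD in A^2; default 1.
#' @param n_points_per_frame Points per frame for the default endpoints.
#' @param closed,open Optional endpoint point sets; the open endpoint is
#'   rescaled along the displacement so the requested spacing holds.
#' @return A [path_reference()].
#' @export
make_path_frames <- function(P = 7, spacing = 1, n_points_per_frame = 4,
                             closed = NULL, open = NULL) {
  if (P < 2) stop("P must be at least 2")
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(closed)) {
    k <- seq_len(n_points_per_frame)
    closed <- cbind(1.5 * k, 0.3 * (-1)^k, 0.1 * k)
    u <- cbind(sin(k), cos(k), 0.5 * sin(2 * k))
    open <- closed + u / sqrt(mean(rowSums(u^2)))   # unit MSD displacement
  }
  disp <- as.matrix(open) - as.matrix(closed)
  m0 <- sum(disp^2) / nrow(disp)
  if (m0 < 1e-12) stop("degenerate endpoints: zero total displacement")
  scale <- sqrt((P - 1)^2 * spacing / m0)
  frames <- lapply(seq_len(P), function(i)
    as.matrix(closed) + disp * scale * (i - 1) / (P - 1))
  path_reference(frames, spacing = spacing)
}

#' Path-progress collective variable on the MSD scale
#'
#' The smoothed progress of a conformation along an ordered set of
#' reference frames,
#' `s(R) = sum_i m_i exp(-lambda MSD(R, f_i)) / sum_i exp(-lambda MSD(R, f_i))`
#' with milestones `m_i = (i - 1) * spacing`, so the value runs from 0 at
#' the bound-state frame to `(P - 1) * spacing` (6 A^2 with the default 7
#' frames at 1 A^2) at the unbound frame.
#'
#' @param frame Point-set matrix, same shape as the reference frames.
#' @param ref A [path_reference()].
#' @return Progress in A^2.
#' @export
path_progress <- function(frame, ref) {
  stopifnot(inherits(ref, "path_reference"))
  ms <- vapply(ref$frames, function(f) msd(frame, f), numeric(1))
  e <- -ref$lambda * ms
  if (max(e) < -700) stop("frame is too far from the reference path")
  w <- exp(e - max(e))
  milestones <- (seq_along(ref$frames) - 1) * ref$spacing
  sum(milestones * w) / sum(w)
}

#' Radial distance from the funnel axis
#'
#' Perpendicular distance of a position from the cylinder axis of the
#' funnel restraint.
#'
#' @param position 3-D point.
#' @param origin Point on the axis.
#' @param direction Axis direction (non-zero; normalized internally).
#' @return Distance in A.
#' @examples
#' funnel_radial(c(7, 3, 4), origin = c(0, 0, 0), direction = c(1, 0, 0)) # 5
#' @export
funnel_radial <- function(position, origin = c(0, 0, 0),
                          direction = c(1, 0, 0)) {
  d <- as.numeric(direction)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("axis direction must be non-zero")
  d <- d / nd
  v <- as.numeric(position) - as.numeric(origin)
  perp <- v - sum(v * d) * d
  sqrt(sum(perp^2))
}

#' Population histogram of a collective-variable series
#'
#' @param values Numeric CV series (non-empty).
#' @param bin_width Positive bin width in the CV's units.
#' @param normalize Also store a density that integrates to one.
#' @param circular Treat values as angles in degrees wrapped at +/-180;
#'   bins are centred on multiples of `bin_width` starting at -180 so that
#'   -179 and +179 degrees share the bin straddling the wrap point.
#' @return An object of class `cv_histogram` with `bin_centers`,
#'   `bin_width`, `counts` and (optionally) `density`.
#' @export
population_histogram <- function(values, bin_width, normalize = FALSE,
                                 circular = FALSE) {
  if (length(values) == 0) stop("empty series")
  if (bin_width <= 0) stop("bin width must be positive")
  if (circular) {
    v <- (values + 180) %% 360 - 180
    shifted <- (v + 180 + bin_width / 2) %% 360
    idx <- floor(shifted / bin_width)
    nb <- ceiling(360 / bin_width)
    idx[idx >= nb] <- nb - 1
    counts <- tabulate(idx + 1, nbins = nb)
    centers <- -180 + (0:(nb - 1)) * bin_width
    centers <- (centers + 180) %% 360 - 180
  } else {
    lo <- floor(min(values) / bin_width) * bin_width
    nb <- max(1, ceiling((max(values) - lo) / bin_width + 1e-9))
    idx <- pmin(floor((values - lo) / bin_width), nb - 1)
    counts <- tabulate(idx + 1, nbins = nb)
    centers <- lo + (seq_len(nb) - 0.5) * bin_width
  }
  out <- list(bin_centers = centers, bin_width = bin_width, counts = counts,
              circular = circular, n = length(values))
  if (normalize) out$density <- counts / (length(values) * bin_width)
  structure(out, class = "cv_histogram")
}

#' @export
print.cv_histogram <- function(x, ...) {
  cat(sprintf("CV histogram: %d bins of width %g, %d samples%s\n",
              length(x$counts), x$bin_width, x$n,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}
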