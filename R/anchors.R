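#' Canonical anchor-point geometry for the unbinding restraints
#'
#' Six reference points control the rotational and translational degrees
#' of freedom of the ligand during the restrained separation: three in the
#' protein (P1, P2 and the fictitious point PC placed 5 A from the ligand
#' centre LC along the unbinding X-axis) and three in the ligand (L1, L2,
#' LC).  The restraint collective variables are the angle
#' alpha(L1, LC, PC), the dihedrals beta(L1, LC, PC, P2) and
#' gamma(L2, L1, LC, PC), the angle theta(LC, PC, P2), the dihedral
#' Theta(LC, PC, P2, P1) and the separation r, the projection of PC - LC
#' on the unbinding axis.
#'
#' @return A named list of 3-D points (an `anchor_frame`).
#' @export
canonical_anchor_frame <- function() {
  structure(list(
    LC = c(0, 0, 0),
    L1 = c(-1.2, 0.8, 0),
    L2 = c(-2.1, -0.6, 0.5),
    PC = c(5, 0, 0),
    P2 = c(9, 1.5, 0.8),
    P1 = c(12, -2, 1.5)), class = "anchor_frame")
}

#' Restraint collective variables of an anchor frame
#'
#' @param frame An `anchor_frame` (list of points `P1, P2, PC, L1, L2, LC`).
#' @param axis Unbinding axis direction for the separation projection.
#' @return Named numeric vector with `alpha`, `beta`, `gamma`, `theta`,
#'   `Theta` (degrees) and `r` (A).
#' @export
anchor_cvs <- function(frame, axis = c(1, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  c(alpha = angle(frame$L1, frame$LC, frame$PC),
    beta = dihedral(frame$L1, frame$LC, frame$PC, frame$P2),
    gamma = dihedral(frame$L2, frame$L1, frame$LC, frame$PC),
    theta = angle(frame$LC, frame$PC, frame$P2),
    Theta = dihedral(frame$LC, frame$PC, frame$P2, frame$P1),
    r = sum((frame$PC - frame$LC) * axis))
}

#' Generate a noisy sequence of anchor frames
#'
#' The canonical geometry perturbed by seeded isotropic Gaussian noise on
#' every point; a fixture generator for the restraint CV machinery.  At
#' `noise = 0` every frame is exactly the canonical frame, so all
#' restraint CVs are constant and the separation projection is exactly
#' 5 A.
#'
#' @param n_frames Number of frames (>= 1).
#' @param noise Standard deviation of the perturbation in A (>= 0).
#' @param seed Integer seed.
#' @return List of `anchor_frame` objects.
#' @export
make_anchor_trajectory <- function(n_frames, noise = 0, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be at least 1")
  if (noise < 0) stop("noise must be non-negative")
  base <- canonical_anchor_frame()
  with_seed(seed, lapply(seq_len(n_frames), function(i) {
    f <- lapply(base, function(p) p + stats::rnorm(3, 0, noise))
    class(f) <- "anchor_frame"
    f
  }))
}
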