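#' One-dimensional free energy profile
#'
#' @param rc Reaction-coordinate values (strictly increasing).
#' @param free_energy Free energy per point, kcal/mol.
#' @param uncertainty Optional standard errors, kcal/mol.
#' @param align Shift so the minimum over finite values is zero.
#' @param cv_name Label of the reaction coordinate.
#' @return An object of class `profile1d`.
#' @export
profile1d <- function(rc, free_energy, uncertainty = NULL, align = TRUE,
                      cv_name = "rc") {
  stopifnot(length(rc) == length(free_energy))
  if (any(diff(rc) <= 0)) stop("rc values must be strictly increasing")
  fe <- as.numeric(free_energy)
  if (align && any(is.finite(fe))) fe <- fe - min(fe[is.finite(fe)])
  structure(list(rc = as.numeric(rc), free_energy = fe,
                 uncertainty = uncertainty, cv_name = cv_name),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  fin <- is.finite(x$free_energy)
  cat(sprintf("1-D profile (%s): %d points on [%g, %g], range %.3g kcal/mol\n",
              x$cv_name, length(x$rc), min(x$rc), max(x$rc),
              diff(range(x$free_energy[fin]))))
  invisible(x)
}

# linear interpolation of a profile at new rc values
profile_interp <- function(profile, rc) {
  stats::approx(profile$rc, profile$free_energy, xout = rc, rule = 2)$y
}

# composite trapezoid
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

in_range <- function(x, range) x >= range[1] & x <= range[2]

#' Binding depth of a separation profile
#'
#' Mean free energy over the bulk plateau minus the minimum over the
#' binding-site range: positive for a binding profile, zero for a flat
#' one.
#'
#' @param profile A [profile1d()].
#' @param site_range,bulk_range Length-2 reaction-coordinate intervals
#'   inside the profile's domain.
#' @return Depth in kcal/mol.
#' @export
pmf_depth <- function(profile, site_range, bulk_range) {
  stopifnot(inherits(profile, "profile1d"))
  si <- in_range(profile$rc, site_range) & is.finite(profile$free_energy)
  bi <- in_range(profile$rc, bulk_range) & is.finite(profile$free_energy)
  if (!any(si)) stop("empty site range")
  if (!any(bi)) stop("empty bulk range")
  mean(profile$free_energy[bi]) - min(profile$free_energy[si])
}
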