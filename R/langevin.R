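#' Parameters for overdamped Langevin (Brownian) dynamics
#'
#' The toy samplers integrate the overdamped Euler-Maruyama update
#' `x <- x - grad(U) * dt / friction + N(0, 2 kT dt / friction)` per
#' coordinate, the desk-scale stand-in for solvated molecular dynamics.
#'
#' @param timestep Integration step in ps (> 0).
#' @param friction Friction coefficient in 1/ps (> 0); the mobility is
#'   `timestep / friction` and the diffusion constant `kT / friction`.
#' @param n_steps Number of integration steps.
#' @param seed Integer seed; identical seeds give bit-identical
#'   trajectories.
#' @param save_stride Store every `save_stride`-th frame.
#' @return An object of class `langevin_params`.
#' @export
langevin_params <- function(timestep = 0.005, friction = 1, n_steps = 10000,
                            seed = 1L, save_stride = 10L) {
  if (timestep <= 0) stop("timestep must be positive")
  if (friction <= 0) stop("friction must be positive")
  if (n_steps < 1) stop("n_steps must be at least 1")
  structure(list(timestep = timestep, friction = friction,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 save_stride = as.integer(save_stride)),
            class = "langevin_params")
}

pot_wrap <- function(potential) {
  if (is.null(potential$periodic)) list() else potential$periodic
}

# run `expr` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a toy potential with overdamped Langevin dynamics
#'
#' @param potential A [toy_potential()].
#' @param params A [langevin_params()].
#' @param conditions A [sim_conditions()]; `conditions$temperature = 0`
#'   turns the update into plain gradient descent.
#' @param bias Optional extra bias: either a list of potential terms (the
#'   same dialect as [toy_potential()] terms, evaluated in C alongside the
#'   potential) or `NULL`.
#' @param x0 Initial coordinates; defaults to the centre of the finite
#'   domain.
#' @param cv_fun Optional function(frame coordinates) returning named CV
#'   values to record per frame.
#' @return A `toy_trajectory`: list with `times` (ps), `coords` (frames x
#'   dimension matrix, frame 1 at t = 0) and optionally `cv_values`.
#'   The frame count is `floor(n_steps / save_stride) + 1`.
#' @examples
#' pot <- toy_potential(1, list(list(type = "harmonic", dims = 1L,
#'                                   a = 2, c = 0)))
#' tr <- langevin_sample(pot, langevin_params(n_steps = 2000, seed = 7),
#'                       sim_conditions())
#' var(tr$coords[, 1])  # approaches kT / k = 0.308 A^2 for long runs
#' @export
langevin_sample <- function(potential, params, conditions = sim_conditions(),
                            bias = NULL, x0 = NULL, cv_fun = NULL) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(params, "langevin_params"))
  if (is.null(x0)) {
    lo <- ifelse(is.finite(potential$domain_lower), potential$domain_lower, -1)
    hi <- ifelse(is.finite(potential$domain_upper), potential$domain_upper, 1)
    x0 <- (lo + hi) / 2
  }
  if (any(x0 < potential$domain_lower | x0 > potential$domain_upper))
    stop("initial coordinates outside the potential domain")
  terms <- potential$terms
  if (!is.null(bias)) terms <- c(terms, bias)
  kT <- conditions$boltzmann_constant * conditions$temperature
  res <- with_seed(params$seed,
    cpp_langevin(terms, as.numeric(x0), params$timestep, params$friction,
                 params$n_steps, params$save_stride, kT,
                 potential$domain_lower, potential$domain_upper, 10,
                 pot_wrap(potential)))
  out <- list(times = res$times, coords = res$coords)
  if (!is.null(cv_fun)) {
    out$cv_values <- t(apply(res$coords, 1, cv_fun))
  }
  structure(out, class = "toy_trajectory")
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf("Langevin trajectory: %d frames x %d coordinate(s), %g ps\n",
              nrow(x$coords), ncol(x$coords), max(x$times)))
  invisible(x)
}
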