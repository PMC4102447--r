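# shared builders and small utilities for the test suite

cond310 <- sim_conditions()

flat_1d <- function(lo = 0, hi = 10) {
  toy_potential(1, list(list(type = "lower_wall", dims = 1L, a = 50, c = lo),
                        list(type = "upper_wall", dims = 1L, a = 50, c = hi)),
                domain_lower = lo - 2, domain_upper = hi + 2)
}

harmonic_1d <- function(k = 2, center = 0) {
  toy_potential(1, list(list(type = "harmonic", dims = 1L, a = k, c = center)),
                domain_lower = center - 20, domain_upper = center + 20)
}

# RMS difference between a profile and an analytic reference after
# removing the free additive constant
rms_vs_reference <- function(rc, fe, ref) {
  ok <- is.finite(fe)
  d <- fe[ok] - ref[ok]
  d <- d - mean(d)
  sqrt(mean(d^2))
}

random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  qr.Q(qr(m)) * sample(c(-1, 1), 1)
}

# analytic Boltzmann density of a 1-D potential on bin centres
boltzmann_density <- function(potential, centers, width, conditions = cond310) {
  fine <- seq(min(centers) - width / 2, max(centers) + width / 2,
              length.out = 8001)
  w <- exp(-conditions$beta *
             potential_energy(potential, matrix(fine, ncol = 1)))
  z <- sum(w) * (fine[2] - fine[1])
  vapply(centers, function(ce) {
    sel <- fine >= ce - width / 2 & fine < ce + width / 2
    sum(w[sel]) * (fine[2] - fine[1]) / z
  }, numeric(1))
}
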