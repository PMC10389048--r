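# Shared fixtures, built in code at test time.

truth_fix <- function() kinetic_parameters(1, 0.2, 2, 5, 1, 0.5)
env_fix <- function() model_environment()

# small noise-free instance on a short grid, for cheap optimizer tests
small_problem <- function(seed = 1, noise_sd = 0) {
  make_problem(truth = truth_fix(), env = env_fix(),
               times = seq(0, 50, length.out = 51), noise_sd = noise_sd,
               seed = seed)
}

sphere2 <- function(x) sum(x^2)

sphere_cfg <- function(seed, colony_size = 20, limit = 10,
                       max_cycles = 100) {
  abc_config(bounds(c(-5, -5), c(5, 5)), colony_size = colony_size,
             limit = limit, max_cycles = max_cycles, seed = seed)
}

withr_like_tempdir <- function() {
  d <- tempfile("beekin-test-")
  dir.create(d)
  d
}

# classical fixed-step RK4, independent of the package's integrator
rk4_reference <- function(deriv, y0, times, h) {
  out <- numeric(length(times))
  out[1] <- y0
  for (j in seq_len(length(times) - 1L)) {
    t <- times[j]; y <- out[j]
    nsteps <- ceiling((times[j + 1L] - t) / h)
    hh <- (times[j + 1L] - t) / nsteps
    for (s in seq_len(nsteps)) {
      k1 <- deriv(t, y)
      k2 <- deriv(t + hh / 2, y + hh / 2 * k1)
      k3 <- deriv(t + hh / 2, y + hh / 2 * k2)
      k4 <- deriv(t + hh, y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[j + 1L] <- y
  }
  out
}
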