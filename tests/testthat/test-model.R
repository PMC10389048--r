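test_that("rate_vin follows the influx rate law", {
  env <- model_environment(g6p = 2)
  p <- kinetic_parameters(2, 0.5, 1, 1, 1, 1)
  expect_equal(rate_vin(p, env), 2 - 0.5 * 2)  # 1.0

  p0 <- kinetic_parameters(2, 0, 1, 1, 1, 1)
  expect_equal(rate_vin(p0, model_environment(g6p = 7)), 2)

  # inhibition exactly cancels the maximal rate
  pc <- kinetic_parameters(2, 0.5, 1, 1, 1, 1)
  expect_equal(rate_vin(pc, model_environment(g6p = 4)), 0)

  # scales with compartment volume
  expect_equal(rate_vin(p, model_environment(cytoplasm_volume = 3, g6p = 2)), 3)
})

test_that("rate_vhk follows the four-term saturation law", {
  env <- model_environment()
  expect_equal(rate_vhk(kinetic_parameters(1, 0, 3, 0, 0, 0), 5, env), 3)
  expect_equal(rate_vhk(kinetic_parameters(1, 0, 0, 1, 1, 1), 1, env), 0)
  # all-ones instance: denominator 1+1+1+1 = 4
  expect_equal(rate_vhk(kinetic_parameters(1, 0, 10, 1, 1, 1), 1, env), 2.5)
})

test_that("rate_vhk is singular-safe and monotone in glucose", {
  env <- model_environment()
  expect_error(rate_vhk(kinetic_parameters(1, 0, 2, 5, 1, 0.5), 0, env),
               "singular")
  expect_error(rate_vhk(kinetic_parameters(1, 0, 2, 5, 1, 0.5), 1,
                        model_environment(atp = 0)),
               "singular")
  # no saturation coefficients -> glci = 0 is fine
  expect_equal(rate_vhk(kinetic_parameters(1, 0, 2, 0, 0, 0), 0, env), 2)

  set.seed(11)
  for (rep in 1:20) {
    p <- as_kinetic_parameters(runif(6, 0.1, 5))
    g <- sort(runif(10, 0.01, 50))
    v <- vapply(g, function(gg) rate_vhk(p, gg, env), 0)
    expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v >= 0))
  }
})

test_that("dglci_dt is the volume-normalized flux balance", {
  env <- model_environment()
  p <- kinetic_parameters(2, 0, 3, 0, 0, 0)
  expect_equal(dglci_dt(p, 1, env), -1)  # 2 - 3 at unit volume
  # steady state: influx 0.8 equals hexokinase rate at Glci = 11
  ps <- truth_fix()
  expect_equal(dglci_dt(ps, 11, env), 0, tolerance = 1e-12)
  # identity at unit volume
  expect_equal(dglci_dt(p, 1, env), rate_vin(p, env) - rate_vhk(p, 1, env))
})

test_that("simulate_glci reproduces closed-form solutions", {
  env <- model_environment()
  times <- seq(0, 20, length.out = 41)
  # all rates zero -> constant series
  flat <- simulate_glci(kinetic_parameters(0, 0, 0, 0, 0, 0), env, times)
  expect_equal(flat$values, rep(env$glci0, length(times)))
  # state-independent net rate -> linear solution
  p <- kinetic_parameters(2, 0, 1, 0, 0.5, 0)
  r <- 2 - 1 / (1 + 0.5 / env$atp)
  lin <- simulate_glci(p, env, times)
  expect_equal(lin$values, env$glci0 + r * times, tolerance = 1e-7)
})

test_that("simulate_glci agrees with independent integrators on a nonlinear instance", {
  env <- model_environment()
  p <- truth_fix()
  times <- seq(0, 5, length.out = 6)
  got <- simulate_glci(p, env, times)
  # fixed-step 4th-order reference at h = 1e-3
  ref <- rk4_reference(function(t, y) dglci_dt(p, max(y, 0), env),
                       env$glci0, times, h = 1e-3)
  expect_equal(got$values, ref, tolerance = 1e-5)
  # established adaptive solver (deSolve lsoda) as a second oracle
  alt <- simulate_glci(p, env, seq(0, 100, length.out = 51), engine = "lsoda")
  dp <- simulate_glci(p, env, seq(0, 100, length.out = 51))
  expect_equal(dp$values, alt$values, tolerance = 1e-6)
})

test_that("the solution is a function of time, not of the output grid", {
  env <- model_environment()
  p <- truth_fix()
  fine <- seq(0, 100, length.out = 201)
  coarse <- fine[seq(1, 201, by = 2)]
  a <- simulate_glci(p, env, fine)
  b <- simulate_glci(p, env, coarse)
  shared <- match(coarse, fine)
  expect_equal(a$values[shared], b$values, tolerance = 1e-7)
})

test_that("negative states are clamped at zero with a warning", {
  # strong G6P inhibition: net efflux drives glucose to zero
  p <- kinetic_parameters(0, 2, 0, 0, 0, 0)
  env <- model_environment(g6p = 1, glci0 = 0.5)
  expect_warning(ts <- simulate_glci(p, env, seq(0, 10, by = 0.5)),
                 "clamped")
  expect_true(all(ts$values >= 0))
  expect_equal(ts$values[length(ts$values)], 0)
})

test_that("parameter and environment constructors validate invariants", {
  expect_error(kinetic_parameters(-1, 0, 1, 1, 1, 1), "non-negative")
  expect_error(as_kinetic_parameters(c(Inf, 1, 1, 1, 1, 1)), "finite")
  expect_error(as_kinetic_parameters(1:5), "6 entries")
  # named input in scrambled order is re-ordered canonically
  x <- c(vhk_vm2 = 2, vin_vm1 = 1, vin_kilg6p = 0.2, vhk_ks2glc = 0.5,
         vhk_km2glc = 5, vhk_km2atp = 1)
  expect_equal(as.numeric(as_kinetic_parameters(x)), c(1, 0.2, 2, 5, 1, 0.5))
  expect_error(model_environment(cytoplasm_volume = 0), "positive")
  expect_error(time_series(c(0, 0, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(time_series(0:2, 1:2), "equal length")
})

test_that("reduced parameter combinations reproduce the hexokinase rate exactly", {
  env <- model_environment(g6p = 0.7, atp = 1.3)
  set.seed(5)
  for (rep in 1:20) {
    p <- as_kinetic_parameters(runif(6, 0.05, 4))
    rp <- reduced_parameters(p, env)
    g <- runif(1, 0.05, 30)
    expect_equal(rate_vhk(p, g, env),
                 rp[["vmax_eff"]] / (1 + rp[["khalf_eff"]] / g),
                 tolerance = 1e-12)
    expect_equal(rp[["influx"]], rate_vin(p, env) / env$cytoplasm_volume)
  }
})
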