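test_that("colony initialization respects bounds, trials and determinism", {
  b <- bounds(c(-2, 0, 10), c(3, 0, 20))  # middle dimension degenerate
  cfg <- abc_config(b, colony_size = 15, limit = 5, max_cycles = 1, seed = 4)
  f <- function(x) sum(x^2)
  set.seed(4)
  col <- init_colony(f, cfg)
  expect_equal(nrow(col$positions), 15)
  expect_true(all(col$positions[, 2] == 0))
  expect_true(all(sweep(col$positions, 2, b$lower, ">=")))
  expect_true(all(sweep(col$positions, 2, b$upper, "<=")))
  expect_true(all(col$trial == 0L))
  expect_equal(col$best$objective, min(col$objective))
  expect_equal(col$evaluations, 15L)

  set.seed(4)
  col2 <- init_colony(f, cfg)
  expect_identical(col, col2)
})

test_that("initialization retries failing draws up to a cap", {
  b <- bounds(c(0, 0), c(1, 1))
  cfg <- abc_config(b, colony_size = 3, limit = 5, max_cycles = 1,
                    init_retries = 50L)
  # fails whenever x1 < 0.5: retried draws eventually land in the good half
  f <- function(x) { if (x[1] < 0.5) stop("bad region"); sum(x) }
  set.seed(1)
  col <- init_colony(f, cfg)
  expect_true(all(col$positions[, 1] >= 0.5))
  expect_gte(col$evaluations, 3L)

  cfg0 <- abc_config(b, colony_size = 3, limit = 5, max_cycles = 1,
                     init_retries = 2L)
  set.seed(1)
  expect_error(init_colony(function(x) stop("always"), cfg0), "failed after")
})

test_that("the neighbor move perturbs one dimension towards a distinct partner", {
  b <- bounds(c(0, 0, 0), c(10, 10, 10))
  cfg <- abc_config(b, colony_size = 3, limit = 5, max_cycles = 1)
  col <- structure(list(positions = rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
                        objective = c(1, 2, 3),
                        fitness = abc_fitness(c(1, 2, 3)),
                        trial = integer(3),
                        best = list(position = c(1, 2, 3), objective = 1),
                        cycle = 0L, evaluations = 3L),
                   class = "abc_colony")
  # forced phi = 0 reproduces the source exactly
  expect_equal(neighbor(col, 1, cfg, dim = 2, partner = 2, phi = 0),
               col$positions[1, ])
  # equal coordinates in the chosen dimension -> unchanged for any phi
  col2 <- col; col2$positions[2, 1] <- 1
  expect_equal(neighbor(col2, 1, cfg, dim = 1, partner = 2, phi = 0.83),
               col2$positions[1, ])
  # forced move matches the update formula with clipping
  v <- neighbor(col, 1, cfg, dim = 3, partner = 3, phi = -1)
  expect_equal(v, c(1, 2, 3 + (-1) * (3 - 9)))  # 3 + 6 = 9

  set.seed(10)
  for (draw in 1:2000) {
    i <- sample(3, 1)
    v <- neighbor(col, i, cfg)
    changed <- which(v != col$positions[i, ])
    expect_lte(length(changed), 1L)  # at most one dimension moves
    expect_true(all(v >= b$lower & v <= b$upper))
  }
})

test_that("greedy selection keeps the fitter source and tracks trials", {
  cur <- list(position = c(1, 1), objective = 2, fitness = abc_fitness(2),
              trial = 3L)
  won <- greedy_select(cur, c(0, 0), 1)
  expect_true(won$accepted)
  expect_equal(won$objective, 1)
  expect_equal(won$trial, 0L)
  lost <- greedy_select(cur, c(0, 0), 5)
  expect_false(lost$accepted)
  expect_equal(lost$position, c(1, 1))
  expect_equal(lost$trial, 4L)
  tie <- greedy_select(cur, c(9, 9), 2)  # exact tie keeps the incumbent
  expect_false(tie$accepted)
  expect_equal(tie$position, c(1, 1))
  expect_equal(tie$trial, 4L)
})

test_that("selection probabilities form a fitness-proportional distribution", {
  col <- list(fitness = c(1, 1, 2))
  expect_equal(selection_probabilities(col), c(0.25, 0.25, 0.5))
  expect_equal(selection_probabilities(list(fitness = rep(3, 5))),
               rep(0.2, 5))
  expect_equal(selection_probabilities(list(fitness = 7)), 1)
  p <- selection_probabilities(list(fitness = runif(20, 0.1, 1)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # invariant under uniform scaling of fitness
  f <- runif(8, 0.1, 2)
  expect_equal(selection_probabilities(list(fitness = f)),
               selection_probabilities(list(fitness = 10 * f)))
  expect_error(selection_probabilities(list(fitness = c(1, 0))), "positive")
})

test_that("employed phase applies forced-outcome greedy selection per source", {
  b <- bounds(rep(-5, 2), rep(5, 2))
  cfg <- abc_config(b, colony_size = 6, limit = 100, max_cycles = 1, seed = 2)
  set.seed(2)
  col <- init_colony(sphere2, cfg)
  # candidates all worse: constant large objective
  worse <- employed_phase(col, function(x) 1e9, cfg)
  expect_equal(worse$positions, col$positions)
  expect_equal(worse$trial, col$trial + 1L)
  expect_equal(worse$evaluations, col$evaluations + 6L)
  # candidates all better: negative objective outranks any SSE fitness
  better <- employed_phase(col, function(x) -1, cfg)
  expect_true(all(better$trial == 0L))
  expect_true(all(better$objective == -1))

  set.seed(77); a <- employed_phase(col, sphere2, cfg)
  set.seed(77); bb <- employed_phase(col, sphere2, cfg)
  expect_identical(a, bb)
})

test_that("onlooker phase concentrates placements on high-fitness sources", {
  b <- bounds(rep(0, 2), rep(1, 2))
  cfg <- abc_config(b, colony_size = 4, limit = 1000, max_cycles = 1)
  col <- structure(list(positions = matrix(runif(8), 4, 2),
                        objective = c(0, 1e6, 1e6, 1e6),
                        fitness = abc_fitness(c(0, 1e6, 1e6, 1e6)),
                        trial = integer(4),
                        best = list(position = c(0, 0), objective = 0),
                        cycle = 0L, evaluations = 4L),
                   class = "abc_colony")
  # source 1 holds virtually all fitness mass
  p <- selection_probabilities(col)
  expect_gt(p[1], 0.999)
  set.seed(3)
  picks <- replicate(10000, sample.int(4, 1, prob = selection_probabilities(col)))
  expect_gte(mean(picks == 1), 0.99)

  # all candidates worse: positions unchanged after the phase
  worse <- onlooker_phase(col, function(x) 1e9, cfg)
  expect_equal(worse$positions, col$positions)
  expect_equal(worse$evaluations, col$evaluations + 4L)

  set.seed(5); a <- onlooker_phase(col, sphere2, cfg)
  set.seed(5); bb <- onlooker_phase(col, sphere2, cfg)
  expect_identical(a, bb)
})

test_that("scout phase abandons only the single most exhausted source", {
  b <- bounds(rep(-1, 2), rep(1, 2))
  cfg <- abc_config(b, colony_size = 4, limit = 10, max_cycles = 1)
  set.seed(9)
  col <- init_colony(sphere2, cfg)

  fresh <- scout_phase(col, sphere2, cfg)  # all trials < limit
  expect_identical(fresh, col)

  col$trial <- c(0L, 10L, 0L, 0L)
  set.seed(1)
  one <- scout_phase(col, sphere2, cfg)
  expect_false(all(one$positions[2, ] == col$positions[2, ]))
  expect_equal(one$trial[2], 0L)
  expect_equal(one$positions[-2, ], col$positions[-2, ])
  expect_equal(one$evaluations, col$evaluations + 1L)

  col$trial <- c(0L, 11L, 15L, 12L)  # only the max-trial source is redrawn
  set.seed(1)
  two <- scout_phase(col, sphere2, cfg)
  expect_equal(two$positions[c(1, 2, 4), ], col$positions[c(1, 2, 4), ])
  expect_equal(two$trial, c(0L, 11L, 0L, 12L))
})

test_that("memorize_best only improves and the trace never increases", {
  b <- bounds(rep(-5, 2), rep(5, 2))
  cfg <- abc_config(b, colony_size = 8, limit = 5, max_cycles = 100, seed = 12)
  res <- run_abc(function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2, cfg)
  expect_true(all(diff(res$trace) <= 0))
  expect_equal(length(res$trace), 101)

  set.seed(1)
  col <- init_colony(sphere2, abc_config(b, 5, 5, 1))
  same <- memorize_best(col)
  expect_identical(same$best, col$best)  # no improvement -> unchanged
  col$objective[3] <- col$best$objective / 2
  col$positions[3, ] <- c(0.1, 0.1)
  upd <- memorize_best(col)
  expect_equal(upd$best$objective, col$objective[3])
  expect_equal(upd$best$position, c(0.1, 0.1))
})

test_that("run_abc is seeded-reproducible with the documented evaluation count", {
  cfg <- sphere_cfg(seed = 31, colony_size = 10, max_cycles = 25)
  r1 <- run_abc(sphere2, cfg)
  r2 <- run_abc(sphere2, cfg)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$evaluations, r2$evaluations)
  # SN + 2*SN*cycles plus one evaluation per scout redraw
  expect_gte(r1$evaluations, 10 + 2 * 10 * 25)
  expect_lte(r1$evaluations, 10 + 2 * 10 * 25 + 25)

  r0 <- run_abc(sphere2, sphere_cfg(seed = 31, max_cycles = 0))
  expect_equal(r0$evaluations, 20L)  # initial colony only
  expect_equal(length(r0$trace), 1L)
})

test_that("every evaluated position stays within bounds across a full run", {
  b <- bounds(c(-1, 2, -3), c(1, 4, -1))
  seen <- list()
  f <- function(x) { seen[[length(seen) + 1L]] <<- x; sum((x - c(0, 3, -2))^2) }
  run_abc(f, abc_config(b, colony_size = 8, limit = 4, max_cycles = 20,
                        seed = 6))
  pos <- do.call(rbind, seen)
  expect_true(all(sweep(pos, 2, b$lower, ">=")))
  expect_true(all(sweep(pos, 2, b$upper, "<=")))
})

test_that("with phi forced to zero and an unreachable limit the colony is a fixed point", {
  b <- bounds(rep(-5, 3), rep(5, 3))
  cfg <- abc_config(b, colony_size = 6, limit = .Machine$integer.max,
                    max_cycles = 1, phi_sampler = function(n) rep(0, n))
  set.seed(8)
  col <- init_colony(sphere2, cfg)
  after <- onlooker_phase(employed_phase(col, sphere2, cfg), sphere2, cfg)
  expect_equal(after$positions, col$positions)
  expect_equal(after$objective, col$objective)
})
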