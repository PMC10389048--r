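make_batch <- function(est, objs, truth, alg = "abc", id = "p1") {
  run_batch(alg, est, objs, truth, problem_id = id)
}

test_that("error rate matches hand computation and a nested-loop oracle", {
  truth <- c(2, 1)
  perfect <- make_batch(rbind(truth, truth), c(0, 0), truth)
  expect_equal(error_rate(perfect), 0)

  one <- make_batch(matrix(3, 1, 1), 0.5, 2)
  expect_equal(error_rate(one), 1)  # (2 - 3)^2

  set.seed(21)
  est <- matrix(rnorm(30), 5, 6)
  tr <- rnorm(6)
  b <- make_batch(est, runif(5), tr)
  loop <- 0
  for (i in 1:5) for (j in 1:6) loop <- loop + (tr[j] - est[i, j])^2
  expect_equal(error_rate(b), loop, tolerance = 1e-12)
  # series reading sums the per-run SSEs
  expect_equal(error_rate(b, on = "series"), sum(b$objectives))
})

test_that("A = e/N and the STD modes satisfy their identities", {
  expect_equal(average_error_rate(0, 10), 0)
  expect_equal(average_error_rate(10, 50), 0.2)
  expect_equal(std_metric(8, 2), 2)               # sqrt(4)
  expect_equal(std_metric(8, 2, mode = "literal"), 4)
  expect_equal(std_metric(0, 7), 0)
  expect_equal(std_metric(0, 7, mode = "literal"), 0)
  expect_error(average_error_rate(1, 0), ">= 1")

  set.seed(3)
  b <- make_batch(matrix(rnorm(24), 4, 6), runif(4), rnorm(6))
  e <- error_rate(b)
  expect_equal(std_metric(e, b$N)^2, average_error_rate(e, b$N),
               tolerance = 1e-12)
})

test_that("metrics are permutation invariant and reward perfect runs", {
  set.seed(14)
  est <- matrix(rnorm(18, sd = 2), 3, 6)
  tr <- rnorm(6)
  objs <- runif(3)
  b1 <- make_batch(est, objs, tr)
  perm <- c(3, 1, 2)
  b2 <- make_batch(est[perm, ], objs[perm], tr)
  expect_equal(error_rate(b1), error_rate(b2))
  expect_equal(evaluation_summary(b1)$A, evaluation_summary(b2)$A)
  expect_equal(evaluation_summary(b1)$STD, evaluation_summary(b2)$STD)

  # adding a run that hits truth exactly: e unchanged, A strictly smaller
  b3 <- make_batch(rbind(est, tr), c(objs, 0), tr)
  expect_equal(error_rate(b3), error_rate(b1))
  expect_lt(evaluation_summary(b3)$A, evaluation_summary(b1)$A)
})

test_that("compare_algorithms flags the per-criterion minimum like a results table", {
  tr <- c(1, 1)
  good <- make_batch(rbind(c(1.1, 1), c(0.9, 1)), c(0.1, 0.2), tr, "abc")
  bad <- make_batch(rbind(c(2, 2), c(0, 0)), c(1, 2), tr, "simplex")
  cmp <- compare_algorithms(list(good, bad))
  expect_equal(cmp$table$algorithm, c("abc", "simplex"))
  # hand computation: e_good = 0.02, e_bad = 4, N = 2
  expect_equal(cmp$table$A, c(0.01, 2))
  expect_equal(cmp$table$STD, sqrt(c(0.01, 2)))
  expect_equal(cmp$table$best_A, c(TRUE, FALSE))
  expect_equal(cmp$table$best_STD, c(TRUE, FALSE))
  expect_true(all(c("algorithm", "A", "STD") %in% names(cmp$table)))

  single <- compare_algorithms(list(good))
  expect_true(single$table$best_A)

  other <- make_batch(rbind(c(2, 2)), 1, c(9, 9), "sa", id = "p2")
  expect_error(compare_algorithms(list(good, other)), "identical problem")
})

test_that("comparison overlays carry experimental plus per-algorithm best fits", {
  prob <- small_problem()
  est <- rbind(as.numeric(prob$truth), as.numeric(prob$truth) * 1.3)
  b <- run_batch("abc", est, c(0, 5), as.numeric(prob$truth),
                 problem_id = "x")
  cmp <- compare_algorithms(list(b), problem = prob)
  expect_named(cmp$overlay, c("experimental", "abc"))
  # best run (objective 0) is the truth: overlay matches the clean series
  expect_equal(cmp$overlay$abc$values, prob$clean_series$values,
               tolerance = 1e-8)
  td <- withr_like_tempdir()
  write_comparison(cmp, td)
  expect_true(file.exists(file.path(td, "comparison.csv")))
  ov <- read.csv(file.path(td, "overlay.csv"))
  expect_setequal(unique(ov$series), c("experimental", "abc"))
  unlink(td, recursive = TRUE)
})
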