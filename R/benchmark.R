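#' Objective-evaluation budget of an ABC configuration
#'
#' \code{colony_size * (1 + 2 * max_cycles)}: initialization plus one
#' employed and one onlooker evaluation per source per cycle. Scout redraws
#' (at most one per cycle) come on top and are reported in each run's
#' \code{evaluations}; the formula is the budget handed to the baselines for
#' budget-matched comparisons.
#'
#' @param config an \code{\link{abc_config}}.
#' @return Integer evaluation budget.
#' @export
abc_evaluation_budget <- function(config) {
  stopifnot(inherits(config, "abc_config"))
  as.integer(config$colony_size * (1L + 2L * config$max_cycles))
}

#' Fit a problem instance with one algorithm
#'
#' Thin dispatcher behind the common optimizer contract. ABC uses
#' \code{abc}'s own configuration; SA and simplex receive the same
#' evaluation budget (budget-matched comparison). The simplex baseline,
#' being deterministic given its start, is started from a seeded uniform
#' draw within the bounds; SA draws its own start from its seed.
#'
#' @param problem a \code{\link{make_problem}} instance.
#' @param algorithm \code{"abc"}, \code{"sa"} or \code{"simplex"}.
#' @param seed integer seed for this run.
#' @param abc an \code{\link{abc_config}} template (bounds are replaced by
#'   the problem's); its budget also caps the baselines.
#' @return An \code{\link{estimation_result}}.
#' @export
fit_problem <- function(problem, algorithm = c("abc", "sa", "simplex"),
                        seed = 1,
                        abc = abc_config(bounds(0, 1), colony_size = 40,
                                         limit = 30, max_cycles = 200)) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(problem, "problem_instance"))
  objective <- make_objective(problem)
  b <- problem$bounds
  budget <- abc_evaluation_budget(abc)
  if (algorithm == "abc") {
    cfg <- abc_config(b, colony_size = abc$colony_size, limit = abc$limit,
                      max_cycles = abc$max_cycles, seed = seed,
                      perturb_all_dims = abc$perturb_all_dims)
    run_abc(objective, cfg)
  } else if (algorithm == "sa") {
    run_simulated_annealing(objective,
                            sa_config(b, seed = seed,
                                      max_evaluations = budget))
  } else {
    start <- with_seed(seed, draw_uniform_position(b))
    res <- run_simplex(objective,
                       simplex_config(start, b, max_evaluations = budget))
    res$seed <- seed
    res
  }
}

#' Benchmark algorithms over repeated seeded runs
#'
#' Runs \code{n_runs} independent estimation runs per algorithm on one
#' problem instance at matched evaluation budgets (run r uses seed
#' \code{seed + r}), collects them into \code{\link{run_batch}} objects and
#' summarizes A and STD per algorithm.
#'
#' @param problem a \code{\link{make_problem}} instance.
#' @param n_runs runs per algorithm (the bundled protocol uses 50).
#' @param algorithms subset of \code{c("abc", "sa", "simplex")}.
#' @param abc ABC configuration template defining the shared budget.
#' @param seed base seed.
#' @param on error-rate reading for the summary table, see
#'   \code{\link{error_rate}}.
#' @param mode STD mode, see \code{\link{std_metric}}.
#' @return A list with class \code{"benchmark_result"}: \code{batches}
#'   (named list of run batches), \code{results} (nested list of
#'   estimation results), \code{comparison} (an
#'   \code{\link{algorithm_comparison}} with overlay), and the echoed
#'   settings.
#' @export
benchmark_algorithms <- function(problem, n_runs = 50,
                                 algorithms = c("abc", "sa", "simplex"),
                                 abc = abc_config(bounds(0, 1),
                                                  colony_size = 40,
                                                  limit = 30,
                                                  max_cycles = 200),
                                 seed = 1,
                                 on = c("parameters", "series"),
                                 mode = c("rms", "literal")) {
  on <- match.arg(on); mode <- match.arg(mode)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  stopifnot(inherits(problem, "problem_instance"), n_runs >= 1)
  problem_id <- sprintf("glci-%s-%d", format(problem$seed),
                        length(problem$times))
  results <- list()
  batches <- list()
  for (alg in algorithms) {
    runs <- lapply(seq_len(n_runs), function(r) {
      fit_problem(problem, alg, seed = seed + r, abc = abc)
    })
    est <- do.call(rbind, lapply(runs, function(x) as.numeric(x$par)))
    colnames(est) <- PARAM_NAMES
    batches[[alg]] <- run_batch(alg, est,
                                vapply(runs, `[[`, 0, "objective"),
                                as.numeric(problem$truth),
                                problem_id = problem_id)
    results[[alg]] <- runs
  }
  comparison <- compare_algorithms(batches, problem = problem, on = on,
                                   mode = mode)
  structure(list(batches = batches, results = results,
                 comparison = comparison, n_runs = n_runs,
                 budget = abc_evaluation_budget(abc), seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d runs/algorithm, budget %d evaluations/run\n",
              x$n_runs, x$budget))
  print(x$comparison)
  invisible(x)
}
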