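#' Estimation result container
#'
#' Common return shape of \code{\link{run_abc}},
#' \code{\link{run_simulated_annealing}} and \code{\link{run_simplex}}: the
#' best parameter vector and objective found, the per-cycle best-so-far
#' trace, the total number of objective evaluations, and an echo of the
#' configuration and seed so any run can be reproduced.
#'
#' @param algorithm character label ("abc", "sa", "simplex").
#' @param par named numeric best position.
#' @param objective best objective value.
#' @param trace numeric best-so-far trace (one entry per cycle boundary,
#'   including the initial state).
#' @param evaluations total objective evaluations performed.
#' @param seed the seed the run was started from (may be NULL).
#' @param config the configuration object used.
#' @param extra optional named list of algorithm-specific diagnostics.
#' @return A list with class \code{"estimation_result"}.
#' @export
estimation_result <- function(algorithm, par, objective, trace, evaluations,
                              seed = NULL, config = NULL, extra = list()) {
  structure(list(algorithm = algorithm, par = par, objective = objective,
                 trace = trace, evaluations = evaluations, seed = seed,
                 config = config, extra = extra),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> %s: objective %.6g after %d evaluations\n",
              x$algorithm, x$objective, x$evaluations))
  cat("  best parameters:\n")
  print(signif(x$par, 6))
  invisible(x)
}

#' Serialize an estimation result to JSON
#'
#' @param result an \code{\link{estimation_result}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_estimation_result <- function(result, path) {
  stopifnot(inherits(result, "estimation_result"))
  cfg <- result$config
  if (!is.null(cfg)) cfg <- unclass(cfg)
  cfg <- Filter(function(x) !is.function(x), cfg)
  if (!is.null(cfg$bounds)) cfg$bounds <- unclass(cfg$bounds)
  payload <- list(
    algorithm = result$algorithm,
    best_parameters = as.list(result$par),
    best_objective = result$objective,
    trace = result$trace,
    evaluations = result$evaluations,
    seed = result$seed,
    config = cfg
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
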