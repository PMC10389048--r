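#' Bundle repeated estimation runs of one algorithm
#'
#' @param algorithm character label.
#' @param estimates matrix of estimated parameter vectors, one row per run
#'   (columns in the documented parameter order), or a list of vectors.
#' @param objectives per-run best objective values (SSE vs the experimental
#'   series).
#' @param truth reference ("experimental") parameter vector.
#' @param problem_id optional identifier of the problem instance; batches
#'   can only be compared when their ids and truths agree.
#' @return A list with class \code{"run_batch"}.
#' @export
run_batch <- function(algorithm, estimates, objectives, truth,
                      problem_id = NULL) {
  if (is.list(estimates)) estimates <- do.call(rbind, estimates)
  estimates <- as.matrix(estimates)
  truth <- as.numeric(truth)
  if (ncol(estimates) != length(truth))
    stop_invalid("estimate dimension does not match truth")
  if (nrow(estimates) != length(objectives))
    stop_invalid("one objective value per run is required")
  if (nrow(estimates) < 1L) stop_invalid("a batch needs at least one run")
  structure(list(algorithm = algorithm, estimates = estimates,
                 objectives = as.numeric(objectives), truth = truth,
                 N = nrow(estimates), problem_id = problem_id),
            class = "run_batch")
}

#' Error rate e over a batch of runs
#'
#' Parameter reading (default): \code{e = sum_runs sum_params
#' (truth - estimate)^2}, the squared deviation between experimental and
#' simulated parameter values summed over all parameters and runs. Series
#' reading (\code{on = "series"}): \code{e = sum_runs SSE_run}, i.e. the
#' per-run glucose time-series discrepancies summed over runs. \code{e = 0}
#' iff every run recovers the reference exactly.
#'
#' @param batch a \code{\link{run_batch}}.
#' @param on \code{"parameters"} (default) or \code{"series"}.
#' @return Non-negative error rate.
#' @export
error_rate <- function(batch, on = c("parameters", "series")) {
  stopifnot(inherits(batch, "run_batch"))
  on <- match.arg(on)
  if (on == "parameters") {
    sum(sweep(batch$estimates, 2L, batch$truth)^2)
  } else {
    sum(batch$objectives)
  }
}

#' Average error rate A = e / N
#'
#' @param e error rate.
#' @param N number of runs (>= 1).
#' @return \code{e / N}.
#' @export
average_error_rate <- function(e, N) {
  if (N < 1) stop_invalid("N must be >= 1")
  e / N
}

#' STD metric over N runs
#'
#' Default mode returns \code{sqrt(e / N)}, a root-mean-squared deviation on
#' the original scale (so \code{STD^2 = A} identically); \code{mode =
#' "literal"} returns \code{e / N}.
#'
#' @param e error rate.
#' @param N number of runs (>= 1).
#' @param mode \code{"rms"} (default) or \code{"literal"}.
#' @return Non-negative STD value.
#' @export
std_metric <- function(e, N, mode = c("rms", "literal")) {
  mode <- match.arg(mode)
  if (N < 1) stop_invalid("N must be >= 1")
  if (mode == "rms") sqrt(e / N) else e / N
}

#' Summarize a batch into e, A and STD
#'
#' @param batch a \code{\link{run_batch}}.
#' @param on error-rate reading, see \code{\link{error_rate}}.
#' @param mode STD mode, see \code{\link{std_metric}}.
#' @return A list with class \code{"evaluation_summary"}: algorithm, e, A,
#'   STD, N, on, mode.
#' @export
evaluation_summary <- function(batch, on = c("parameters", "series"),
                               mode = c("rms", "literal")) {
  on <- match.arg(on); mode <- match.arg(mode)
  e <- error_rate(batch, on)
  structure(list(algorithm = batch$algorithm, e = e,
                 A = average_error_rate(e, batch$N),
                 STD = std_metric(e, batch$N, mode),
                 N = batch$N, on = on, mode = mode),
            class = "evaluation_summary")
}

#' Compare algorithms over matched run batches
#'
#' Builds the per-algorithm table of average error rate A and STD, flags the
#' minimum of each criterion, and (when a problem instance is supplied)
#' attaches overlay series: the experimental glucose trajectory plus each
#' algorithm's best-fit simulation.
#'
#' @param batches list of \code{\link{run_batch}} objects solving the
#'   identical problem instance.
#' @param problem optional \code{\link{make_problem}} instance used to
#'   simulate each algorithm's best-run fit for the overlay.
#' @param on error-rate reading, see \code{\link{error_rate}}.
#' @param mode STD mode, see \code{\link{std_metric}}.
#' @return A list with class \code{"algorithm_comparison"}: \code{table}
#'   (data.frame algorithm/A/STD/N/on/mode with \code{best_A}/\code{best_STD}
#'   flags) and \code{overlay} (named list of \code{\link{time_series}}, or
#'   NULL).
#' @export
compare_algorithms <- function(batches, problem = NULL,
                               on = c("parameters", "series"),
                               mode = c("rms", "literal")) {
  on <- match.arg(on); mode <- match.arg(mode)
  stopifnot(length(batches) >= 1L, all(vapply(batches, inherits, TRUE,
                                              "run_batch")))
  truth0 <- batches[[1L]]$truth
  id0 <- batches[[1L]]$problem_id
  for (btch in batches) {
    if (length(btch$truth) != length(truth0) || any(btch$truth != truth0) ||
        !identical(btch$problem_id, id0))
      stop_invalid("batches do not solve the identical problem instance")
  }
  summaries <- lapply(batches, evaluation_summary, on = on, mode = mode)
  tab <- data.frame(
    algorithm = vapply(summaries, `[[`, "", "algorithm"),
    A = vapply(summaries, `[[`, 0, "A"),
    STD = vapply(summaries, `[[`, 0, "STD"),
    N = vapply(summaries, `[[`, 0L, "N"),
    on = on, mode = mode, stringsAsFactors = FALSE)
  tab$best_A <- tab$A == min(tab$A)
  tab$best_STD <- tab$STD == min(tab$STD)

  overlay <- NULL
  if (!is.null(problem)) {
    stopifnot(inherits(problem, "problem_instance"))
    overlay <- list(experimental = problem$experimental_series)
    for (btch in batches) {
      ibest <- which.min(btch$objectives)
      fit <- simulate_glci(as_kinetic_parameters(btch$estimates[ibest, ]),
                           problem$env, problem$times)
      overlay[[btch$algorithm]] <- fit
    }
  }
  structure(list(table = tab, overlay = overlay),
            class = "algorithm_comparison")
}

#' @export
print.algorithm_comparison <- function(x, ...) {
  tab <- x$table
  tab$A <- signif(tab$A, 5)
  tab$STD <- signif(tab$STD, 5)
  tab$best <- ifelse(x$table$best_A & x$table$best_STD, "*", "")
  print(tab[, c("algorithm", "A", "STD", "N", "on", "mode", "best")],
        row.names = FALSE)
  cat("(* = lowest A and STD)\n")
  invisible(x)
}

#' Plot the concentration overlay of a comparison
#'
#' Experimental glucose series (points) with each algorithm's best-fit
#' simulation (lines), concentration against time.
#'
#' @param x an \code{\link{compare_algorithms}} result carrying an overlay.
#' @param ... passed to \code{graphics::plot}.
#' @return \code{x}, invisibly.
#' @export
plot.algorithm_comparison <- function(x, ...) {
  if (is.null(x$overlay))
    stop_invalid("comparison carries no overlay; pass `problem` to compare_algorithms()")
  ov <- x$overlay
  exp_ts <- ov$experimental
  alg <- setdiff(names(ov), "experimental")
  ylim <- range(unlist(lapply(ov, `[[`, "values")))
  graphics::plot(exp_ts$times, exp_ts$values, pch = 1, cex = 0.5,
                 xlab = "time (s)", ylab = "Glci (mmol/L)", ylim = ylim, ...)
  for (j in seq_along(alg)) {
    graphics::lines(ov[[alg[j]]]$times, ov[[alg[j]]]$values, col = j + 1,
                    lwd = 2)
  }
  graphics::legend("bottomright", legend = c("experimental", alg),
                   col = c(1, seq_along(alg) + 1),
                   pch = c(1, rep(NA, length(alg))),
                   lty = c(NA, rep(1, length(alg))), bty = "n")
  invisible(x)
}

#' Write a comparison report to CSV and JSON
#'
#' @param comparison an \code{\link{compare_algorithms}} result.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  stopifnot(inherits(comparison, "algorithm_comparison"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(comparison$table, file.path(dir, "comparison.csv"),
            row.names = FALSE)
  jsonlite::write_json(comparison$table, file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(comparison$overlay)) {
    ov <- comparison$overlay
    long <- do.call(rbind, lapply(names(ov), function(nm) {
      data.frame(series = nm, time = ov[[nm]]$times, value = ov[[nm]]$values,
                 stringsAsFactors = FALSE)
    }))
    write.csv(long, file.path(dir, "overlay.csv"), row.names = FALSE)
  }
  invisible(dir)
}
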