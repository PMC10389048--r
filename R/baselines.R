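#' Simulated Annealing configuration
#'
#' @param bounds a \code{\link{bounds}} search box.
#' @param initial_temperature starting temperature; \code{NULL} (default)
#'   uses the objective value of the starting point (or 1 if that is 0).
#' @param cooling_rate geometric cooling factor in (0, 1).
#' @param steps_per_temperature proposals evaluated at each temperature.
#' @param step_scale proposal standard deviation as a fraction of the bound
#'   width, per dimension.
#' @param seed optional integer seed.
#' @param max_evaluations objective-evaluation budget (including the
#'   starting point).
#' @return A list with class \code{"sa_config"}.
#' @export
sa_config <- function(bounds, initial_temperature = NULL,
                      cooling_rate = 0.95, steps_per_temperature = 20,
                      step_scale = 0.1, seed = NULL,
                      max_evaluations = 10000) {
  stopifnot(inherits(bounds, "bounds"))
  if (!is.null(initial_temperature) && initial_temperature <= 0)
    stop_invalid("initial_temperature must be positive")
  if (cooling_rate <= 0 || cooling_rate >= 1)
    stop_invalid("cooling_rate must be in (0, 1)")
  if (step_scale <= 0) stop_invalid("step_scale must be positive")
  structure(list(bounds = bounds, initial_temperature = initial_temperature,
                 cooling_rate = cooling_rate,
                 steps_per_temperature = as.integer(steps_per_temperature),
                 step_scale = step_scale, seed = seed,
                 max_evaluations = as.integer(max_evaluations)),
            class = "sa_config")
}

#' Simulated Annealing baseline optimizer
#'
#' Metropolis acceptance with geometric cooling on the bounded problem.
#' The walk starts from a uniform draw within the bounds; proposals are
#' Gaussian steps (sd = \code{step_scale} x bound width per dimension)
#' clipped to the bounds. A proposal with objective increase \code{delta} is
#' accepted with probability \code{exp(-delta / T)}; as \code{T -> 0} the
#' walk reduces to pure descent. Runs until the evaluation budget is spent.
#'
#' @param objective_fn function mapping a position to a finite objective.
#' @param config an \code{\link{sa_config}}.
#' @return An \code{\link{estimation_result}} (trace = best-so-far after
#'   each temperature block).
#' @export
run_simulated_annealing <- function(objective_fn, config) {
  stopifnot(inherits(config, "sa_config"))
  b <- config$bounds
  width <- b$upper - b$lower
  with_seed(config$seed, {
    x <- draw_uniform_position(b)
    fx <- objective_fn(x)
    evals <- 1L
    temp <- config$initial_temperature
    if (is.null(temp)) temp <- if (fx > 0) fx else 1
    best_x <- x; best_f <- fx
    trace <- best_f
    while (evals < config$max_evaluations) {
      for (s in seq_len(config$steps_per_temperature)) {
        if (evals >= config$max_evaluations) break
        prop <- clip_to_bounds(x + rnorm(length(x), 0,
                                         config$step_scale * width), b)
        fp <- objective_fn(prop)
        evals <- evals + 1L
        delta <- fp - fx
        accept <- delta <= 0 ||
          (temp > 0 && runif(1) < exp(-delta / temp))
        if (accept) { x <- prop; fx <- fp }
        if (fx < best_f) { best_f <- fx; best_x <- x }
      }
      trace <- c(trace, best_f)
      temp <- temp * config$cooling_rate
    }
    if (length(best_x) == 6L) names(best_x) <- PARAM_NAMES
    estimation_result("sa", best_x, best_f, trace, evals,
                      seed = config$seed, config = config)
  })
}

#' Nelder-Mead simplex configuration
#'
#' Standard coefficient defaults: reflection 1, expansion 2, contraction
#' 0.5, shrink 0.5.
#'
#' @param initial_guess numeric starting point (within bounds).
#' @param bounds a \code{\link{bounds}} search box.
#' @param reflection,expansion,contraction,shrink Nelder-Mead coefficients
#'   (reflection > 0, expansion > 1, contraction and shrink in (0, 1)).
#' @param tolerance termination threshold on the objective spread across
#'   simplex vertices.
#' @param max_evaluations objective-evaluation budget.
#' @param initial_step initial simplex edge per dimension as a fraction of
#'   the bound width.
#' @return A list with class \code{"simplex_config"}.
#' @export
simplex_config <- function(initial_guess, bounds, reflection = 1,
                           expansion = 2, contraction = 0.5, shrink = 0.5,
                           tolerance = 1e-10, max_evaluations = 2000,
                           initial_step = 0.05) {
  stopifnot(inherits(bounds, "bounds"))
  if (reflection <= 0 || expansion <= 1 ||
      contraction <= 0 || contraction >= 1 || shrink <= 0 || shrink >= 1)
    stop_invalid("invalid Nelder-Mead coefficients")
  initial_guess <- as.numeric(initial_guess)
  if (length(initial_guess) != length(bounds$lower))
    stop_invalid("initial_guess dimension does not match bounds")
  structure(list(initial_guess = initial_guess, bounds = bounds,
                 reflection = reflection, expansion = expansion,
                 contraction = contraction, shrink = shrink,
                 tolerance = tolerance,
                 max_evaluations = as.integer(max_evaluations),
                 initial_step = initial_step),
            class = "simplex_config")
}

#' Nelder-Mead simplex baseline optimizer
#'
#' Standard Nelder-Mead on the bounded problem: every candidate vertex is
#' clipped to the bounds before evaluation. Deterministic given the initial
#' guess. Terminates when the objective spread across vertices falls below
#' \code{tolerance}, when the simplex collapses geometrically (reported via
#' \code{extra$degenerate}), or when the evaluation budget is spent.
#'
#' @param objective_fn function mapping a position to a finite objective.
#' @param config a \code{\link{simplex_config}}.
#' @return An \code{\link{estimation_result}} (trace = best vertex after
#'   each iteration).
#' @export
run_simplex <- function(objective_fn, config) {
  stopifnot(inherits(config, "simplex_config"))
  b <- config$bounds
  d <- length(config$initial_guess)
  width <- b$upper - b$lower
  x0 <- clip_to_bounds(config$initial_guess, b)

  verts <- matrix(rep(x0, d + 1L), nrow = d + 1L, byrow = TRUE)
  for (j in seq_len(d)) {
    step <- config$initial_step * width[j]
    if (step == 0) step <- max(config$initial_step * max(abs(x0[j]), 1), 1e-8)
    cand <- x0[j] + step
    if (cand > b$upper[j]) cand <- x0[j] - step
    verts[j + 1L, j] <- min(max(cand, b$lower[j]), b$upper[j])
  }
  fvals <- apply(verts, 1L, objective_fn)
  evals <- d + 1L
  trace <- min(fvals)
  degenerate <- FALSE

  centroid <- function(v, worst) colMeans(v[-worst, , drop = FALSE])

  while (evals < config$max_evaluations) {
    ord <- order(fvals)
    verts <- verts[ord, , drop = FALSE]
    fvals <- fvals[ord]
    if (max(fvals) - min(fvals) < config$tolerance) break
    size <- max(abs(sweep(verts, 2L, verts[1L, ])))
    if (size < 1e-14 * max(1, max(abs(verts[1L, ])))) {
      degenerate <- TRUE
      break
    }
    worst <- d + 1L
    xc <- centroid(verts, worst)
    xr <- clip_to_bounds(xc + config$reflection * (xc - verts[worst, ]), b)
    fr <- objective_fn(xr); evals <- evals + 1L
    if (fr < fvals[1L]) {
      xe <- clip_to_bounds(xc + config$expansion * (xr - xc), b)
      fe <- objective_fn(xe); evals <- evals + 1L
      if (fe < fr) { verts[worst, ] <- xe; fvals[worst] <- fe }
      else { verts[worst, ] <- xr; fvals[worst] <- fr }
    } else if (fr < fvals[d]) {
      verts[worst, ] <- xr; fvals[worst] <- fr
    } else {
      if (fr < fvals[worst]) {
        xk <- clip_to_bounds(xc + config$contraction * (xr - xc), b)
      } else {
        xk <- clip_to_bounds(xc + config$contraction * (verts[worst, ] - xc), b)
      }
      fk <- objective_fn(xk); evals <- evals + 1L
      if (fk < min(fr, fvals[worst])) {
        verts[worst, ] <- xk; fvals[worst] <- fk
      } else {
        for (j in 2L:(d + 1L)) {
          verts[j, ] <- clip_to_bounds(
            verts[1L, ] + config$shrink * (verts[j, ] - verts[1L, ]), b)
          fvals[j] <- objective_fn(verts[j, ])
          evals <- evals + 1L
          if (evals >= config$max_evaluations) break
        }
      }
    }
    trace <- c(trace, min(fvals))
  }
  ibest <- which.min(fvals)
  par <- verts[ibest, ]
  if (length(par) == 6L) names(par) <- PARAM_NAMES
  estimation_result("simplex", par, fvals[ibest], cummin(trace), evals,
                    seed = NULL, config = config,
                    extra = list(degenerate = degenerate))
}
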