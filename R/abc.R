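#' Box bounds for the search space
#'
#' @param lower,upper finite numeric vectors with \code{lower <= upper}
#'   elementwise.
#' @return A list with class \code{"bounds"}.
#' @export
bounds <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper))
    stop_invalid("lower and upper must have equal length")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop_invalid("bounds must be finite")
  if (any(lower > upper))
    stop_invalid("lower bound exceeds upper bound")
  structure(list(lower = lower, upper = upper), class = "bounds")
}

clip_to_bounds <- function(x, b) pmin(pmax(x, b$lower), b$upper)

#' ABC optimizer configuration
#'
#' Colony size, abandonment limit and cycle count default to the bundled
#' protocol (colony 40, limit 30, 20 cycles); all are overridable. The
#' number of onlooker placements per cycle equals the colony size, so one
#' cycle costs exactly \code{2 * colony_size} objective evaluations plus at
#' most one scout redraw.
#'
#' @param bounds a \code{\link{bounds}} object defining the search box.
#' @param colony_size number of food sources SN (>= 2).
#' @param limit abandonment threshold on the per-source trial counter (>= 1).
#' @param max_cycles number of employed/onlooker/scout cycles (>= 0;
#'   0 evaluates the initial colony only).
#' @param seed optional integer seed; a single seeded generator drives all
#'   phases in a fixed call order, so runs are bit-reproducible.
#' @param perturb_all_dims if TRUE the neighbor move perturbs every dimension
#'   (with independent phi draws) instead of one random dimension.
#' @param phi_sampler optional function \code{n -> numeric(n)} replacing the
#'   default \code{runif(n, -1, 1)} draw of the step factor; a diagnostic
#'   hook for discrete or degenerate step sets.
#' @param init_retries how many fresh draws to attempt when the objective
#'   fails at an initial position before giving up.
#' @return A list with class \code{"abc_config"}.
#' @export
abc_config <- function(bounds, colony_size = 40, limit = 30, max_cycles = 20,
                       seed = NULL, perturb_all_dims = FALSE,
                       phi_sampler = NULL, init_retries = 25L) {
  stopifnot(inherits(bounds, "bounds"))
  if (colony_size < 2) stop_invalid("colony_size must be >= 2")
  if (limit < 1) stop_invalid("limit must be >= 1")
  if (max_cycles < 0) stop_invalid("max_cycles must be >= 0")
  structure(list(bounds = bounds, colony_size = as.integer(colony_size),
                 limit = as.integer(limit),
                 max_cycles = as.integer(max_cycles), seed = seed,
                 perturb_all_dims = isTRUE(perturb_all_dims),
                 phi_sampler = phi_sampler,
                 init_retries = as.integer(init_retries)),
            class = "abc_config")
}

draw_uniform_position <- function(b) {
  b$lower + runif(length(b$lower)) * (b$upper - b$lower)
}

eval_with_retry <- function(objective_fn, b, x, retries) {
  for (attempt in seq_len(retries + 1L)) {
    f <- tryCatch(objective_fn(x), error = function(e) e)
    if (!inherits(f, "error")) return(list(position = x, objective = f,
                                           draws = attempt))
    if (attempt > retries)
      stop_invalid("objective evaluation failed after ", retries,
                   " fresh draws: ", conditionMessage(f))
    x <- draw_uniform_position(b)
  }
}

#' Initialize an ABC colony
#'
#' Draws \code{colony_size} positions uniformly per-dimension within the
#' bounds, evaluates each, zeroes all trial counters and memorizes the
#' colony minimum as the initial best. Consumes the current RNG stream; seed
#' control belongs to \code{\link{run_abc}}.
#'
#' @param objective_fn function mapping a position to a finite objective.
#' @param config an \code{\link{abc_config}}.
#' @return A list with class \code{"abc_colony"}: positions matrix (one row
#'   per source), objective, fitness and trial vectors, best-so-far record,
#'   cycle index and evaluation count.
#' @export
init_colony <- function(objective_fn, config) {
  stopifnot(inherits(config, "abc_config"))
  b <- config$bounds
  sn <- config$colony_size
  d <- length(b$lower)
  positions <- matrix(NA_real_, nrow = sn, ncol = d)
  objective <- numeric(sn)
  evals <- 0L
  for (i in seq_len(sn)) {
    res <- eval_with_retry(objective_fn, b, draw_uniform_position(b),
                           config$init_retries)
    positions[i, ] <- res$position
    objective[i] <- res$objective
    evals <- evals + res$draws
  }
  ibest <- which.min(objective)
  structure(list(positions = positions, objective = objective,
                 fitness = abc_fitness(objective),
                 trial = integer(sn),
                 best = list(position = positions[ibest, ],
                             objective = objective[ibest]),
                 cycle = 0L, evaluations = evals),
            class = "abc_colony")
}

#' Generate a neighbor candidate position
#'
#' The canonical ABC move: the candidate equals source \code{i}'s position
#' except in one randomly chosen dimension \code{d}, where
#' \code{v_d = x_id + phi * (x_id - x_kd)} with \code{phi ~ U[-1, 1]} and a
#' uniformly drawn partner \code{k != i}; the result is clipped to the
#' bounds. \code{dim}, \code{partner} and \code{phi} may be forced for
#' testing/diagnostics; when forced, no random draw is consumed for that
#' component.
#'
#' @param colony an \code{"abc_colony"}.
#' @param i index of the source to perturb.
#' @param config an \code{\link{abc_config}}.
#' @param dim,partner,phi optional forced choices.
#' @return Numeric candidate position within bounds.
#' @export
neighbor <- function(colony, i, config, dim = NULL, partner = NULL,
                     phi = NULL) {
  sn <- nrow(colony$positions)
  if (sn < 2) stop_invalid("neighbor search needs a colony of size >= 2")
  d_total <- ncol(colony$positions)
  x <- colony$positions[i, ]
  dims <- if (config$perturb_all_dims) seq_len(d_total)
          else if (!is.null(dim)) as.integer(dim)
          else sample.int(d_total, 1L)
  k <- if (!is.null(partner)) as.integer(partner) else {
    k0 <- sample.int(sn - 1L, 1L)
    if (k0 >= i) k0 + 1L else k0
  }
  if (k == i) stop_invalid("partner index must differ from i")
  nphi <- length(dims)
  ph <- if (!is.null(phi)) rep_len(phi, nphi)
        else if (!is.null(config$phi_sampler)) config$phi_sampler(nphi)
        else runif(nphi, -1, 1)
  v <- x
  v[dims] <- x[dims] + ph * (x[dims] - colony$positions[k, dims])
  clip_to_bounds(v, config$bounds)
}

#' Greedy selection between a food source and its candidate
#'
#' Keeps the candidate iff its fitness strictly exceeds the incumbent's
#' (ties keep the incumbent); the survivor's trial counter is reset to 0 on
#' replacement and incremented by 1 otherwise, so stagnation is detectable.
#'
#' @param current list with fields \code{position}, \code{objective},
#'   \code{fitness}, \code{trial}.
#' @param candidate_position numeric position of the candidate.
#' @param candidate_objective finite objective value of the candidate.
#' @return The surviving source as a list (same fields), plus a logical
#'   \code{accepted}.
#' @export
greedy_select <- function(current, candidate_position, candidate_objective) {
  cand_fit <- abc_fitness(candidate_objective)
  if (cand_fit > current$fitness) {
    list(position = candidate_position, objective = candidate_objective,
         fitness = cand_fit, trial = 0L, accepted = TRUE)
  } else {
    list(position = current$position, objective = current$objective,
         fitness = current$fitness, trial = current$trial + 1L,
         accepted = FALSE)
  }
}

#' Roulette-wheel selection probabilities
#'
#' \code{p_i = fit_i / sum_j fit_j} over the colony's fitness values.
#'
#' @param colony an \code{"abc_colony"}.
#' @return Numeric probabilities summing to 1.
#' @export
selection_probabilities <- function(colony) {
  fit <- colony$fitness
  if (any(fit <= 0) || !all(is.finite(fit)))
    stop_invalid("all fitness values must be positive and finite")
  tot <- sum(fit)
  if (tot <= 0) stop_invalid("degenerate colony: zero total fitness")
  fit / tot
}

source_at <- function(colony, i) {
  list(position = colony$positions[i, ], objective = colony$objective[i],
       fitness = colony$fitness[i], trial = colony$trial[i])
}

replace_source <- function(colony, i, src) {
  colony$positions[i, ] <- src$position
  colony$objective[i] <- src$objective
  colony$fitness[i] <- src$fitness
  colony$trial[i] <- src$trial
  colony
}

#' Employed-bee phase
#'
#' Visits each food source exactly once: generates a neighbor candidate,
#' evaluates it, and applies greedy selection. Costs exactly
#' \code{colony_size} objective evaluations.
#'
#' @param colony an \code{"abc_colony"}.
#' @param objective_fn the objective function.
#' @param config an \code{\link{abc_config}}.
#' @return The updated colony.
#' @export
employed_phase <- function(colony, objective_fn, config) {
  for (i in seq_len(nrow(colony$positions))) {
    v <- neighbor(colony, i, config)
    fv <- objective_fn(v)
    colony <- replace_source(colony, i, greedy_select(source_at(colony, i), v, fv))
    colony$evaluations <- colony$evaluations + 1L
  }
  colony
}

#' Onlooker-bee phase
#'
#' Performs \code{colony_size} onlooker placements. Each placement selects a
#' source by roulette wheel over the current selection probabilities
#' (recomputed after every replacement), generates a neighbor, evaluates it
#' and applies greedy selection. Costs exactly \code{colony_size} objective
#' evaluations.
#'
#' @inheritParams employed_phase
#' @return The updated colony.
#' @export
onlooker_phase <- function(colony, objective_fn, config) {
  sn <- nrow(colony$positions)
  for (placement in seq_len(sn)) {
    p <- selection_probabilities(colony)
    i <- sample.int(sn, 1L, prob = p)
    v <- neighbor(colony, i, config)
    fv <- objective_fn(v)
    colony <- replace_source(colony, i, greedy_select(source_at(colony, i), v, fv))
    colony$evaluations <- colony$evaluations + 1L
  }
  colony
}

#' Memorize-best phase
#'
#' Updates the best-so-far record iff some source's objective is strictly
#' lower, so the best-so-far trace is non-increasing across cycles.
#'
#' @param colony an \code{"abc_colony"}.
#' @return The updated colony.
#' @export
memorize_best <- function(colony) {
  i <- which.min(colony$objective)
  if (colony$objective[i] < colony$best$objective) {
    colony$best <- list(position = colony$positions[i, ],
                        objective = colony$objective[i])
  }
  colony
}

#' Scout-bee phase
#'
#' Among sources whose trial counter has reached the abandonment limit, the
#' single most-exhausted one (largest trial; lowest index on ties) is
#' replaced by a fresh uniform draw with trial 0 — at most one scout per
#' cycle, so the colony is never mass-replaced. The best-so-far record is
#' kept separately and thus never lost to abandonment.
#'
#' @inheritParams employed_phase
#' @return The updated colony.
#' @export
scout_phase <- function(colony, objective_fn, config) {
  exhausted <- which(colony$trial >= config$limit)
  if (length(exhausted) == 0L) return(colony)
  i <- exhausted[which.max(colony$trial[exhausted])]
  res <- eval_with_retry(objective_fn, config$bounds,
                         draw_uniform_position(config$bounds),
                         config$init_retries)
  colony <- replace_source(colony, i, list(position = res$position,
                                           objective = res$objective,
                                           fitness = abc_fitness(res$objective),
                                           trial = 0L))
  colony$evaluations <- colony$evaluations + res$draws
  if (res$objective < colony$best$objective)
    colony$best <- list(position = res$position, objective = res$objective)
  colony
}

#' Run the Artificial Bee Colony optimizer
#'
#' Loops employed -> onlooker -> memorize-best -> scout for
#' \code{max_cycles} cycles from a freshly initialized colony. The total
#' evaluation count is \code{colony_size} (initialization) plus
#' \code{2 * colony_size} per cycle plus one per scout redraw.
#'
#' @param objective_fn function mapping a numeric position (length =
#'   dimension of the bounds) to a finite objective value; lower is better.
#' @param config an \code{\link{abc_config}}.
#' @return An \code{\link{estimation_result}} whose \code{trace} holds the
#'   best-so-far objective at initialization and after each cycle
#'   (length \code{max_cycles + 1}).
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- abc_config(bounds(c(-5, -5), c(5, 5)), colony_size = 20,
#'                   limit = 10, max_cycles = 50, seed = 1)
#' run_abc(sphere, cfg)$objective
#' @export
run_abc <- function(objective_fn, config) {
  stopifnot(inherits(config, "abc_config"))
  with_seed(config$seed, {
    colony <- init_colony(objective_fn, config)
    trace <- numeric(config$max_cycles + 1L)
    trace[1L] <- colony$best$objective
    cyc <- 0L
    while (cyc < config$max_cycles) {
      colony <- employed_phase(colony, objective_fn, config)
      colony <- onlooker_phase(colony, objective_fn, config)
      colony <- memorize_best(colony)
      colony <- scout_phase(colony, objective_fn, config)
      cyc <- cyc + 1L
      colony$cycle <- cyc
      trace[cyc + 1L] <- colony$best$objective
    }
    par <- colony$best$position
    if (length(par) == 6L) names(par) <- PARAM_NAMES
    estimation_result("abc", par, colony$best$objective, trace,
                      colony$evaluations, seed = config$seed, config = config)
  })
}
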