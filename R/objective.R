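#' Sum-of-squares estimation objective
#'
#' Nonlinear least-squares objective between an experimental and a simulated
#' series sampled on the identical time grid:
#' \code{f(X) = sum_i (y_exp_i - y_sim_i)^2}. No interpolation or weighting
#' is applied; mismatched grids raise an alignment error rather than being
#' silently interpolated.
#'
#' @param y_exp,y_sim \code{\link{time_series}} objects (or plain numeric
#'   vectors of equal length).
#' @return The SSE in (mmol/L)^2; zero iff the series are identical.
#' @examples
#' a <- time_series(0:3, c(1, 2, 3, 4))
#' b <- time_series(0:3, c(1, 2, 3, 5))
#' sse(a, b)  # 1
#' @export
sse <- function(y_exp, y_sim) {
  if (inherits(y_exp, "time_series") && inherits(y_sim, "time_series")) {
    if (length(y_exp$times) != length(y_sim$times) ||
        any(y_exp$times != y_sim$times))
      stop_invalid("alignment error: series are not on the identical time grid")
    a <- y_exp$values; b <- y_sim$values
  } else {
    a <- as.numeric(if (inherits(y_exp, "time_series")) y_exp$values else y_exp)
    b <- as.numeric(if (inherits(y_sim, "time_series")) y_sim$values else y_sim)
    if (length(a) != length(b))
      stop_invalid("alignment error: series lengths differ")
  }
  sum((a - b)^2)
}

#' Gaussian observation-noise specification
#'
#' Additive zero-mean i.i.d. Gaussian noise on each sampled concentration.
#'
#' @param sigma standard deviation (mmol/L), >= 0.
#' @param seed optional integer RNG seed for reproducible draws.
#' @return A list with class \code{"noise_spec"}.
#' @export
noise_spec <- function(sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0)
    stop_invalid("sigma must be finite and >= 0")
  structure(list(sigma = sigma, seed = seed), class = "noise_spec")
}

#' Add observation noise to a time series
#'
#' Perturbs each value with an independent N(0, sigma^2) draw. With
#' \code{sigma = 0} the input is returned unchanged; with a seed in the
#' \code{noise_spec} the output is reproducible and the caller's RNG state is
#' left untouched.
#'
#' @param series a \code{\link{time_series}}.
#' @param noise a \code{\link{noise_spec}}.
#' @return A perturbed \code{\link{time_series}}.
#' @export
add_noise <- function(series, noise) {
  stopifnot(inherits(series, "time_series"), inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(series)
  eps <- with_seed(noise$seed,
                   rnorm(length(series$values), mean = 0, sd = noise$sigma))
  time_series(series$times, series$values + eps, series$species_id)
}

#' ABC fitness transform
#'
#' Maps an objective value to a selection weight: \code{1/(1+f)} for
#' \code{f >= 0} and \code{1 + |f|} for \code{f < 0}. Strictly decreasing in
#' \code{f} on the non-negative half-line, so for an SSE objective the
#' fitness lies in (0, 1].
#'
#' @param f finite objective value(s).
#' @return Fitness value(s) in (0, Inf).
#' @examples
#' abc_fitness(c(0, 3, -2))  # 1, 0.25, 3
#' @export
abc_fitness <- function(f) {
  if (any(!is.finite(f)))
    stop_invalid("objective value must be finite")
  ifelse(f >= 0, 1 / (1 + f), 1 + abs(f))
}

#' Build the SSE objective function for an estimation problem
#'
#' Binds the experimental series and the model/environment of a
#' \code{\link{make_problem}} instance into a function mapping a parameter
#' vector (in the documented order) to the SSE against the experimental
#' series on its own time grid.
#'
#' @param problem a \code{\link{make_problem}} instance.
#' @param rtol,atol integration tolerances used for every candidate
#'   evaluation.
#' @return A function \code{f(x) -> SSE} accepting a numeric vector of
#'   length 6.
#' @export
make_objective <- function(problem, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(problem, "problem_instance"))
  ev <- env_vec(problem$env)
  times <- problem$experimental_series$times
  yexp <- problem$experimental_series$values
  function(x) {
    y <- .glci_integrate(as.numeric(x), ev, times, rtol, atol)
    sum((yexp - y)^2)
  }
}
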