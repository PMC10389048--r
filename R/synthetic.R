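#' Search bounds from an initial guess
#'
#' The bundled bounding scheme: per parameter, lower = guess/10 and
#' upper = guess*10, so the box always contains the guess and spans two
#' decades around it. Requires a strictly positive guess.
#'
#' @param guess strictly positive numeric parameter vector.
#' @return A \code{\link{bounds}} object.
#' @examples
#' bounds_from_guess(c(5, 1))  # lower 0.5, 0.1; upper 50, 10
#' @export
bounds_from_guess <- function(guess) {
  guess <- as.numeric(guess)
  if (any(!is.finite(guess)) || any(guess <= 0))
    stop_invalid("the x10 / /10 bounding scheme requires a strictly positive guess")
  bounds(guess / 10, guess * 10)
}

#' Default ground-truth kinetic parameters of the benchmark instance
#'
#' A documented positive six-parameter vector chosen so the default
#' instance produces a smooth saturating glucose trajectory (rise from
#' 1 mmol/L towards a steady state of 11 mmol/L over ~100 s, relaxation
#' time ~70 s). Purely a benchmark choice; override freely.
#'
#' @return A \code{\link{kinetic_parameters}} vector.
#' @export
default_truth <- function() {
  kinetic_parameters(vin_vm1 = 1.0, vin_kilg6p = 0.2, vhk_vm2 = 2.0,
                     vhk_km2glc = 5.0, vhk_km2atp = 1.0, vhk_ks2glc = 0.5)
}

#' Generate a self-contained synthetic estimation problem
#'
#' Emulates the benchmark setup end to end: simulate the glucose ODE at the
#' ground-truth parameters on a fixed sampling grid, optionally add
#' zero-mean Gaussian observation noise, perturb the truth into an initial
#' guess, and derive the search bounds from that guess (x10 / /10). All
#' randomness (noise, then guess factors) is driven by \code{seed}, so
#' instances are bit-reproducible.
#'
#' @param truth ground-truth \code{\link{kinetic_parameters}}.
#' @param env \code{\link{model_environment}}.
#' @param times sampling grid (s); default 0..100 s at 201 points.
#' @param noise_sd Gaussian noise standard deviation (mmol/L); \code{NULL}
#'   (default) uses 1\% of the clean series' dynamic range; 0 gives a
#'   noise-free instance.
#' @param guess_perturbation factor g >= 1: the initial guess is the truth
#'   times per-parameter log-uniform factors in [1/g, g]. With the default
#'   g = 3 the derived bounds always contain the truth.
#' @param seed integer seed.
#' @return A list with class \code{"problem_instance"}: truth, env, times,
#'   clean_series, experimental_series, noise_sd, initial_guess, bounds,
#'   seed.
#' @examples
#' prob <- make_problem(seed = 1)
#' prob$noise_sd
#' @export
make_problem <- function(truth = default_truth(), env = model_environment(),
                         times = seq(0, 100, length.out = 201),
                         noise_sd = NULL, guess_perturbation = 3, seed = 1) {
  truth <- as_kinetic_parameters(truth)
  stopifnot(inherits(env, "model_environment"))
  if (any(truth <= 0))
    stop_invalid("make_problem requires a strictly positive truth vector")
  if (guess_perturbation < 1)
    stop_invalid("guess_perturbation must be >= 1")
  clean <- simulate_glci(truth, env, times)
  if (is.null(noise_sd))
    noise_sd <- 0.01 * diff(range(clean$values))
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_invalid("noise_sd must be finite and >= 0")
  inst <- with_seed(seed, {
    experimental <- add_noise(clean, noise_spec(noise_sd))
    g <- guess_perturbation
    factors <- if (g == 1) rep(1, 6L) else exp(runif(6L, -log(g), log(g)))
    guess <- as.numeric(truth) * factors
    names(guess) <- PARAM_NAMES
    list(experimental = experimental, guess = guess)
  })
  structure(list(truth = truth, env = env, times = as.numeric(times),
                 clean_series = clean,
                 experimental_series = inst$experimental,
                 noise_sd = noise_sd,
                 initial_guess = inst$guess,
                 bounds = bounds_from_guess(inst$guess),
                 guess_perturbation = guess_perturbation,
                 seed = seed),
            class = "problem_instance")
}

#' @export
print.problem_instance <- function(x, ...) {
  cat(sprintf("<problem_instance> %d points on [%g, %g] s, noise sd %.4g mmol/L, seed %s\n",
              length(x$times), min(x$times), max(x$times), x$noise_sd,
              format(x$seed)))
  cat("  truth:        ", paste(sprintf("%s=%.3g", names(x$truth), x$truth),
                                collapse = ", "), "\n")
  cat("  initial guess:", paste(sprintf("%.3g", x$initial_guess),
                                collapse = ", "), "\n")
  invisible(x)
}
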