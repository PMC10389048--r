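#' Kinetic parameters of the glucose subsystem
#'
#' The six estimable kinetic parameters of the bundled glucose subsystem of
#' the yeast fermentation pathway, in a fixed documented order:
#' \code{vin_vm1} (maximal glucose influx rate, mmol/L/s),
#' \code{vin_kilg6p} (G6P inhibition coefficient of the influx),
#' \code{vhk_vm2} (maximal hexokinase rate, mmol/L/s),
#' \code{vhk_km2glc} (glucose half-saturation, mmol/L),
#' \code{vhk_km2atp} (ATP half-saturation, mmol/L),
#' \code{vhk_ks2glc} (glucose/ATP coupling coefficient, mmol/L).
#'
#' @param vin_vm1,vin_kilg6p,vhk_vm2,vhk_km2glc,vhk_km2atp,vhk_ks2glc
#'   non-negative finite numerics.
#' @return A named numeric vector of length 6 with class
#'   \code{"kinetic_parameters"}.
#' @examples
#' kinetic_parameters(1, 0.2, 2, 5, 1, 0.5)
#' @export
kinetic_parameters <- function(vin_vm1, vin_kilg6p, vhk_vm2,
                               vhk_km2glc, vhk_km2atp, vhk_ks2glc) {
  x <- c(vin_vm1 = vin_vm1, vin_kilg6p = vin_kilg6p, vhk_vm2 = vhk_vm2,
         vhk_km2glc = vhk_km2glc, vhk_km2atp = vhk_km2atp,
         vhk_ks2glc = vhk_ks2glc)
  as_kinetic_parameters(x)
}

#' Coerce a numeric vector to kinetic parameters
#'
#' @param x numeric vector of length 6, optionally named; unnamed vectors are
#'   taken in the documented parameter order.
#' @return A \code{"kinetic_parameters"} vector.
#' @export
as_kinetic_parameters <- function(x) {
  x <- unlist(x, use.names = TRUE)
  if (length(x) != 6L)
    stop_invalid("kinetic parameters must have exactly 6 entries")
  if (is.null(names(x)) || !all(nzchar(names(x)))) {
    names(x) <- PARAM_NAMES
  } else {
    if (!setequal(names(x), PARAM_NAMES))
      stop_invalid("unknown parameter names: ",
                   paste(setdiff(names(x), PARAM_NAMES), collapse = ", "))
    x <- x[PARAM_NAMES]
  }
  if (any(!is.finite(x)))
    stop_invalid("kinetic parameters must be finite")
  if (any(x < 0))
    stop_invalid("kinetic parameters must be non-negative")
  structure(as.numeric(stats::setNames(x, PARAM_NAMES)),
            names = PARAM_NAMES, class = "kinetic_parameters")
}

#' Model environment for the glucose subsystem
#'
#' Fixed (non-estimated) quantities of the simulation: the cytoplasm
#' compartment volume, the clamped G6P and ATP concentrations, and the
#' initial intracellular glucose concentration. G6P and ATP appear in the
#' rate laws but their dynamics are not part of the subsystem, so both are
#' held constant. Defaults (1 L, 1 mmol/L each) are documented placeholders
#' and freely configurable.
#'
#' @param cytoplasm_volume compartment size in liters, must be > 0.
#' @param g6p,atp fixed metabolite concentrations (mmol/L), >= 0.
#' @param glci0 initial intracellular glucose (mmol/L), >= 0.
#' @return A list with class \code{"model_environment"}.
#' @export
model_environment <- function(cytoplasm_volume = 1, g6p = 1, atp = 1,
                              glci0 = 1) {
  vals <- c(cytoplasm_volume, g6p, atp, glci0)
  if (any(!is.finite(vals)))
    stop_invalid("model environment values must be finite")
  if (cytoplasm_volume <= 0)
    stop_invalid("cytoplasm_volume must be positive")
  if (any(c(g6p, atp, glci0) < 0))
    stop_invalid("g6p, atp and glci0 must be non-negative")
  structure(list(cytoplasm_volume = cytoplasm_volume, g6p = g6p, atp = atp,
                 glci0 = glci0),
            class = "model_environment")
}

#' Concentration time series
#'
#' @param times strictly increasing sampling instants (seconds), length >= 2.
#' @param values concentrations (mmol/L), one per instant.
#' @param species_id species label, e.g. \code{"Glci"}.
#' @return A list with class \code{"time_series"}.
#' @export
time_series <- function(times, values, species_id = "Glci") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L)
    stop_invalid("a time series needs at least 2 instants")
  if (length(times) != length(values))
    stop_invalid("times and values must have equal length")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop_invalid("times must be finite and strictly increasing")
  structure(list(times = times, values = values,
                 species_id = as.character(species_id)[1]),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d points, t in [%g, %g] s, value in [%g, %g] mmol/L\n",
              x$species_id, length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

env_vec <- function(env) {
  c(env$cytoplasm_volume, env$g6p, env$atp, env$glci0)
}

#' Glucose influx rate Vin
#'
#' \code{Vin = cytoplasm_volume * (vm1 - kilg6p * G6P)} in mmol/s. The flux
#' may be negative (net efflux when G6P inhibition exceeds the maximal rate);
#' callers decide whether to clip.
#'
#' @param params \code{\link{kinetic_parameters}}.
#' @param env \code{\link{model_environment}}.
#' @return Flux in mmol/s.
#' @export
rate_vin <- function(params, env) {
  params <- as_kinetic_parameters(params)
  stopifnot(inherits(env, "model_environment"))
  env$cytoplasm_volume * (params[["vin_vm1"]] - params[["vin_kilg6p"]] * env$g6p)
}

#' Hexokinase rate Vhk
#'
#' Reversible-hexokinase saturation form with the full four-term denominator:
#' \code{Vhk = V * vm2 / (1 + km2glc/Glci + km2atp/ATP +
#' ks2glc*km2atp/(Glci*ATP))}. Non-negative for non-negative inputs and
#' monotonically non-decreasing in \code{glci}.
#'
#' @param params \code{\link{kinetic_parameters}}.
#' @param glci intracellular glucose concentration (mmol/L); must be > 0
#'   whenever a saturation coefficient involving glucose is nonzero.
#' @param env \code{\link{model_environment}}.
#' @return Flux in mmol/s.
#' @export
rate_vhk <- function(params, glci, env) {
  params <- as_kinetic_parameters(params)
  stopifnot(inherits(env, "model_environment"))
  if (!is.finite(glci) || glci < 0)
    stop_invalid("glci must be finite and non-negative")
  km2glc <- params[["vhk_km2glc"]]
  km2atp <- params[["vhk_km2atp"]]
  ks2glc <- params[["vhk_ks2glc"]]
  if (glci == 0 && (km2glc > 0 || ks2glc > 0))
    stop_invalid("singular rate: glci = 0 with nonzero saturation coefficient")
  if (env$atp == 0 && (km2atp > 0 || ks2glc > 0))
    stop_invalid("singular rate: atp = 0 with nonzero saturation coefficient")
  denom <- 1
  if (km2glc > 0) denom <- denom + km2glc / glci
  if (km2atp > 0) denom <- denom + km2atp / env$atp
  if (ks2glc > 0 && km2atp > 0)
    denom <- denom + ks2glc * km2atp / (glci * env$atp)
  env$cytoplasm_volume * params[["vhk_vm2"]] / denom
}

#' Glucose balance right-hand side
#'
#' \code{dGlci/dt = (Vin - Vhk) / cytoplasm_volume} in mmol/L/s.
#'
#' @inheritParams rate_vhk
#' @return Rate of change of intracellular glucose (mmol/L/s).
#' @export
dglci_dt <- function(params, glci, env) {
  (rate_vin(params, env) - rate_vhk(params, glci, env)) / env$cytoplasm_volume
}

#' Simulate the glucose concentration time series
#'
#' Integrates the one-state glucose balance from \code{env$glci0} and returns
#' the concentration at exactly the requested instants. The default engine is
#' a compiled adaptive Dormand-Prince 5(4) integrator; \code{engine =
#' "lsoda"} routes through \code{deSolve::ode} instead (useful as an
#' independent cross-check). Should the state dip below zero it is clamped at
#' 0 with a warning, since concentrations are non-negative.
#'
#' @param params \code{\link{kinetic_parameters}}.
#' @param env \code{\link{model_environment}}.
#' @param times strictly increasing output instants (s); \code{times[1]} is
#'   the initial time.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param engine \code{"dp45"} (compiled, default) or \code{"lsoda"}
#'   (deSolve).
#' @return A \code{\link{time_series}} for species \code{"Glci"}.
#' @examples
#' p <- kinetic_parameters(1, 0.2, 2, 5, 1, 0.5)
#' ts <- simulate_glci(p, model_environment(), seq(0, 100, by = 5))
#' @export
simulate_glci <- function(params, env, times, rtol = 1e-8, atol = 1e-10,
                          engine = c("dp45", "lsoda")) {
  engine <- match.arg(engine)
  params <- as_kinetic_parameters(params)
  stopifnot(inherits(env, "model_environment"))
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop_invalid("times must be strictly increasing with length >= 2")
  if (engine == "dp45") {
    vals <- .glci_integrate(unclass(params), env_vec(env), times, rtol, atol)
    if (isTRUE(attr(vals, "clamped")))
      warning("state clamped at 0 during integration (non-negative concentration)")
    attr(vals, "clamped") <- NULL
  } else {
    rhs <- function(t, y, parms) {
      g <- max(y[1], 0)
      list(dglci_rhs(params, g, env))
    }
    sol <- deSolve::ode(y = c(glci = env$glci0), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
    vals <- as.numeric(sol[, "glci"])
    if (any(vals < 0)) {
      warning("state clamped at 0 during integration (non-negative concentration)")
      vals <- pmax(vals, 0)
    }
  }
  time_series(times, vals, "Glci")
}

# rate evaluation without the constructor/validation overhead of rate_vhk,
# tolerant of glci == 0 (uses the saturating limit); internal RHS use only.
dglci_rhs <- function(params, glci, env) {
  km2glc <- params[["vhk_km2glc"]]
  km2atp <- params[["vhk_km2atp"]]
  ks2glc <- params[["vhk_ks2glc"]]
  vin <- env$cytoplasm_volume *
    (params[["vin_vm1"]] - params[["vin_kilg6p"]] * env$g6p)
  if (glci <= 0 && (km2glc > 0 || (ks2glc > 0 && km2atp > 0))) {
    vhk <- 0
  } else {
    denom <- 1
    if (km2glc > 0) denom <- denom + km2glc / glci
    if (km2atp > 0) denom <- denom + km2atp / env$atp
    if (ks2glc > 0 && km2atp > 0)
      denom <- denom + ks2glc * km2atp / (glci * env$atp)
    vhk <- env$cytoplasm_volume * params[["vhk_vm2"]] / denom
  }
  (vin - vhk) / env$cytoplasm_volume
}

#' Identifiable parameter combinations of the glucose subsystem
#'
#' With G6P and ATP clamped, the six raw kinetic parameters enter the glucose
#' balance only through three combinations, so only these are structurally
#' identifiable from a single glucose trajectory:
#' \describe{
#'   \item{influx}{\code{vm1 - kilg6p * g6p} (net state-independent influx,
#'     mmol/L/s)}
#'   \item{vmax_eff}{\code{vm2 / (1 + km2atp/atp)} (effective maximal
#'     hexokinase rate, mmol/L/s)}
#'   \item{khalf_eff}{\code{(km2glc + ks2glc*km2atp/atp) / (1 + km2atp/atp)}
#'     (effective glucose half-saturation, mmol/L)}
#' }
#' The hexokinase rate then reads \code{vmax_eff / (1 + khalf_eff/Glci)}.
#'
#' @param params \code{\link{kinetic_parameters}}.
#' @param env \code{\link{model_environment}}.
#' @return Named numeric vector \code{c(influx, vmax_eff, khalf_eff)}.
#' @export
reduced_parameters <- function(params, env) {
  params <- as_kinetic_parameters(params)
  stopifnot(inherits(env, "model_environment"))
  if (env$atp == 0 && (params[["vhk_km2atp"]] > 0 || params[["vhk_ks2glc"]] > 0))
    stop_invalid("singular reduction: atp = 0 with nonzero saturation coefficient")
  satp <- if (params[["vhk_km2atp"]] > 0) params[["vhk_km2atp"]] / env$atp else 0
  denom <- 1 + satp
  c(influx = params[["vin_vm1"]] - params[["vin_kilg6p"]] * env$g6p,
    vmax_eff = params[["vhk_vm2"]] / denom,
    khalf_eff = (params[["vhk_km2glc"]] + params[["vhk_ks2glc"]] * satp) / denom)
}
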