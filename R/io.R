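#' Write a time series as CSV
#'
#' Dialect: header \code{time,species,value}; time in seconds, value in
#' mmol/L, UTF-8, "." decimal separator.
#'
#' @param series a \code{\link{time_series}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_time_series <- function(series, path) {
  stopifnot(inherits(series, "time_series"))
  df <- data.frame(time = series$times, species = series$species_id,
                   value = series$values, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a time series from CSV
#'
#' @param path CSV file in the \code{time,species,value} dialect.
#' @param species optional species id to select when the file holds several.
#' @return A \code{\link{time_series}}.
#' @export
read_time_series <- function(path, species = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("time", "species", "value")
  if (!all(need %in% names(df)))
    stop_invalid("expected CSV columns time,species,value in ", path)
  if (is.null(species)) {
    ids <- unique(df$species)
    if (length(ids) > 1L)
      stop_invalid("file holds several species (", paste(ids, collapse = ", "),
                   "); pass `species`")
    species <- ids[1L]
  }
  df <- df[df$species == species, , drop = FALSE]
  if (nrow(df) == 0L) stop_invalid("species ", species, " not found in ", path)
  df <- df[order(df$time), , drop = FALSE]
  time_series(df$time, df$value, species)
}

#' Serialize a problem instance to a directory
#'
#' Writes \code{truth.json}, \code{config.json} and \code{experimental.csv}
#' (standard time-series CSV) so an instance can be re-loaded or shared.
#'
#' @param problem a \code{\link{make_problem}} instance.
#' @param dir output directory (created if missing).
#' @param force overwrite an existing serialized instance.
#' @return \code{dir}, invisibly.
#' @export
write_problem <- function(problem, dir, force = FALSE) {
  stopifnot(inherits(problem, "problem_instance"))
  if (dir.exists(dir) && file.exists(file.path(dir, "config.json")) && !force)
    stop_invalid("directory ", dir, " already holds a problem; use force = TRUE")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(as.list(unclass(problem$truth)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- list(env = unclass(problem$env), times = problem$times,
              noise_sd = problem$noise_sd,
              guess_perturbation = problem$guess_perturbation,
              initial_guess = as.list(problem$initial_guess),
              bounds = unclass(problem$bounds), seed = problem$seed)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_time_series(problem$experimental_series,
                    file.path(dir, "experimental.csv"))
  invisible(dir)
}

#' Load a problem instance from a directory
#'
#' Inverse of \code{\link{write_problem}}; the experimental series is read
#' back from CSV (not re-simulated), so the loaded instance reproduces the
#' stored one.
#'
#' @param dir directory written by \code{\link{write_problem}}.
#' @return A \code{"problem_instance"}.
#' @export
read_problem <- function(dir) {
  truth <- as_kinetic_parameters(unlist(
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  env <- model_environment(cfg$env$cytoplasm_volume, cfg$env$g6p,
                           cfg$env$atp, cfg$env$glci0)
  experimental <- read_time_series(file.path(dir, "experimental.csv"))
  guess <- unlist(cfg$initial_guess)[PARAM_NAMES]
  structure(list(truth = truth, env = env, times = as.numeric(cfg$times),
                 clean_series = simulate_glci(truth, env, cfg$times),
                 experimental_series = experimental,
                 noise_sd = cfg$noise_sd,
                 initial_guess = guess,
                 bounds = bounds(cfg$bounds$lower, cfg$bounds$upper),
                 guess_perturbation = cfg$guess_perturbation,
                 seed = cfg$seed),
            class = "problem_instance")
}

#' Write a run manifest
#'
#' Records what ran: command label, configuration snapshot, seeds, artifact
#' paths, package/R versions and a timestamp, as JSON next to the outputs,
#' so any CLI invocation can be reproduced.
#'
#' @param path manifest file path.
#' @param command character label of the invocation.
#' @param config list snapshot of the effective configuration.
#' @param seeds named list/vector of seeds in play.
#' @param artifacts character vector of output paths.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seeds = list(),
                           artifacts = character()) {
  payload <- list(command = command, config = config, seeds = seeds,
                  artifacts = as.list(artifacts),
                  versions = list(beekin = as.character(packageVersion("beekin")),
                                  R = paste(R.version$major, R.version$minor,
                                            sep = ".")),
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
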