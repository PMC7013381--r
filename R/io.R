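#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration with blocks `parameters` (any subset
#' of the [acr_params()] fields), `initial_state` (any subset of `W`, `R`,
#' `S`, `V1`, `V2`), `simulation` (`t_end`, `n_samples`, `rtol`, `atol`,
#' `extinction_threshold`) and `transfers` (lists/records with `time` and
#' `dilution`). Unknown keys are rejected by name; missing fields are
#' filled with package defaults and recorded, so the resolved configuration
#' is fully self-describing and round-trips exactly through
#' [write_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return Object of class `acr_config`: list with elements `parameters`
#'   (an `acr_params`), `initial_state` (named state vector), `simulation`
#'   (complete list), `transfers` (data frame or `NULL`) and attribute
#'   `defaults_used` naming every defaulted field.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json", call. = FALSE)
  if (!is.list(raw)) stop("config parse failure: not a mapping", call. = FALSE)
  resolve_config(raw)
}

#' @keywords internal
resolve_config <- function(raw) {
  blocks <- c("parameters", "initial_state", "simulation", "transfers")
  unknown <- setdiff(names(raw), blocks)
  if (length(unknown))
    stop("unknown config key: '", unknown[1L], "' (allowed: ",
         paste(blocks, collapse = ", "), ")", call. = FALSE)
  defaults_used <- character(0)

  par_fields <- names(formals(acr_params))
  pr <- raw$parameters
  if (is.null(pr)) pr <- list()
  unknown <- setdiff(names(pr), par_fields)
  if (length(unknown))
    stop("unknown parameter key: '", unknown[1L], "'", call. = FALSE)
  defaults_used <- c(defaults_used,
                     paste0("parameters.", setdiff(par_fields, names(pr))))
  params <- do.call(acr_params, pr)

  st_fields <- c("W", "R", "S", "V1", "V2")
  st <- raw$initial_state
  if (is.null(st)) st <- list()
  unknown <- setdiff(names(st), st_fields)
  if (length(unknown))
    stop("unknown initial_state key: '", unknown[1L], "'", call. = FALSE)
  defaults_used <- c(defaults_used,
                     paste0("initial_state.", setdiff(st_fields, names(st))))
  st_full <- utils::modifyList(list(W = 1e3, R = 0, S = 0, V1 = 0, V2 = 0),
                               st)
  initial <- do.call(acr_state, st_full)

  sim_defaults <- list(t_end = 30, n_samples = 301L, rtol = 1e-8,
                       atol = 1e-10, extinction_threshold = 1e-3)
  sm <- raw$simulation
  if (is.null(sm)) sm <- list()
  unknown <- setdiff(names(sm), names(sim_defaults))
  if (length(unknown))
    stop("unknown simulation key: '", unknown[1L], "'", call. = FALSE)
  defaults_used <- c(defaults_used,
                     paste0("simulation.",
                            setdiff(names(sim_defaults), names(sm))))
  sim <- utils::modifyList(sim_defaults, sm)

  tr <- raw$transfers
  if (!is.null(tr)) {
    tr <- as.data.frame(tr)
    tr <- validate_transfers(tr, sim$t_end)
    if (nrow(tr) == 0L) tr <- NULL
  }

  structure(list(parameters = params, initial_state = initial,
                 simulation = sim, transfers = tr),
            defaults_used = sort(defaults_used), class = "acr_config")
}

#' Write a resolved configuration
#'
#' Serialises an `acr_config` so that [load_config()] reads back an
#' identical resolved configuration (round-trip idempotence).
#'
#' @param config an `acr_config` from [load_config()] or [resolve_config()].
#' @param path output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "acr_config"))
  out <- list(parameters = unclass(config$parameters),
              initial_state = as.list(config$initial_state),
              simulation = config$simulation)
  if (!is.null(config$transfers))
    out$transfers <- list(time = config$transfers$time,
                          dilution = config$transfers$dilution)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(out, path, precision = 17)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  else stop("config must be written as .yaml/.yml or .json", call. = FALSE)
  invisible(path)
}

#' Simulate from a configuration
#'
#' Convenience wrapper tying the configuration layer to the simulator.
#'
#' @param config an `acr_config`.
#' @return An `acr_trajectory`.
#' @export
simulate_config <- function(config) {
  stopifnot(inherits(config, "acr_config"))
  sm <- config$simulation
  acr_simulate(config$initial_state, config$parameters, t_end = sm$t_end,
               sample_times = seq(0, sm$t_end, length.out = sm$n_samples),
               transfers = config$transfers, rtol = sm$rtol, atol = sm$atol,
               extinction_threshold = sm$extinction_threshold)
}

# 17 significant digits: enough for exact double round-trip through text.
#' @keywords internal
format_full <- function(x) sprintf("%.17g", x)

#' Write a table with full-precision numerics
#'
#' Comma-separated, LF newlines, numeric columns serialised with 17
#' significant digits so that a write/read round trip reproduces every
#' double bit-exactly (to 1 ulp).
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (cn in names(out))
    if (is.double(out[[cn]])) out[[cn]] <- format_full(out[[cn]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a table with schema enforcement
#'
#' @param path CSV path.
#' @param schema named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"`, `"character"`, `"logical"`); extra
#'   columns are allowed.
#' @return Data frame with at least the schema columns, coerced to the
#'   declared types.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(df))
    if (length(miss))
      stop("schema error: missing column '", miss[1L], "'", call. = FALSE)
    for (cn in names(schema)) {
      coerce <- switch(schema[[cn]], numeric = as.numeric,
                       integer = as.integer, character = as.character,
                       logical = as.logical,
                       stop("unknown schema type: ", schema[[cn]],
                            call. = FALSE))
      if (schema[[cn]] == "logical" && is.numeric(df[[cn]]) &&
          nrow(df) > 0L)
        stop("schema error: column '", cn, "' is not logical",
             call. = FALSE)
      v <- suppressWarnings(coerce(df[[cn]]))
      if (nrow(df) > 0L && any(is.na(v) & !is.na(df[[cn]])))
        stop("schema error: column '", cn, "' is not ", schema[[cn]],
             call. = FALSE)
      df[[cn]] <- v
    }
  }
  df
}

#' Write a trajectory and its parameter sidecar
#'
#' The trajectory goes to `path` as a full-precision CSV (columns `t`, `W`,
#' `R`, `S`, `V1`, `V2`, `N`, `V`); the parameters, events and extinction
#' threshold go to a JSON sidecar at `paste0(path, ".json")`, so every run
#' is self-describing.
#'
#' @param traj an `acr_trajectory`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "acr_trajectory"))
  write_table(as.data.frame(traj), path)
  side <- list(parameters = unclass(attr(traj, "params")),
               extinction_threshold = attr(traj, "extinction_threshold"),
               events = attr(traj, "events"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path (the JSON sidecar is expected alongside).
#' @return An `acr_trajectory`.
#' @export
read_trajectory <- function(path) {
  cols <- c("t", "W", "R", "S", "V1", "V2", "N", "V")
  df <- read_table(path, schema = stats::setNames(rep("numeric", 8), cols))
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("trajectory sidecar not found: ", side_path, call. = FALSE)
  side <- jsonlite::fromJSON(side_path)
  ev <- as.data.frame(side$events)
  if (nrow(ev) == 0L)
    ev <- data.frame(time = numeric(0), kind = character(0),
                     detail = character(0))
  structure(df,
            params = do.call(acr_params, as.list(side$parameters)),
            events = ev,
            extinction_threshold = side$extinction_threshold,
            class = c("acr_trajectory", "data.frame"))
}

#' Write a run manifest
#'
#' Records everything needed to re-execute a run: the package version, the
#' fully resolved configuration, the seed, the MD5 digests of the files the
#' run produced, and a timestamp.
#'
#' @param config an `acr_config`.
#' @param path manifest output path (JSON).
#' @param seed the seed used (or `NULL`).
#' @param files character vector of produced file paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, seed = NULL, files = character(0)) {
  stopifnot(inherits(config, "acr_config"))
  digests <- if (length(files)) as.list(tools::md5sum(files)) else NULL
  man <- list(
    package = "acrdyn",
    version = as.character(utils::packageVersion("acrdyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = list(parameters = unclass(config$parameters),
                  initial_state = as.list(config$initial_state),
                  simulation = config$simulation,
                  transfers = if (is.null(config$transfers)) NULL else
                    list(time = config$transfers$time,
                         dilution = config$transfers$dilution)),
    defaults_used = attr(config, "defaults_used"),
    file_digests = digests)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Re-create the configuration recorded in a manifest
#'
#' @param path manifest path written by [write_manifest()].
#' @return The `acr_config` the manifest records.
#' @export
config_from_manifest <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  resolve_config(man$config)
}
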