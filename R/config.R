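#' Load a simulation configuration file
#'
#' Reads a YAML or JSON configuration holding up to three blocks --
#' `params` (one key per [gbm_params()] field), `schedule` (keys of
#' [make_schedule()]) and `domain` (`shape`, `seed`, `b0`, `h` for the
#' synthetic phantom, or `raster` + `label_map` for an imported slice) --
#' validates everything against the model invariants, and rejects unknown
#' keys.  Missing keys take the package defaults; every defaulted value is
#' reported via `message()` when `verbose = TRUE` so a run's effective
#' configuration is always on record.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.  An empty file yields
#'   the full default configuration.
#' @param verbose Log the effective configuration (default `TRUE`).
#' @return A list with elements `params` (`gbm_params`), `schedule`
#'   (`gbm_schedule`) and `domain_options` (named list).
#' @export
load_config <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use YAML or JSON)",
         call. = FALSE)
  }
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), c("params", "schedule", "domain"))
  if (length(unknown) > 0) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  par_cfg <- cfg$params %||% list()
  bad <- setdiff(names(par_cfg), names(formals(gbm_params)))
  if (length(bad) > 0) {
    stop("unknown parameter key(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(par_cfg$relax_rate) && identical(par_cfg$relax_rate, "Inf")) {
    par_cfg$relax_rate <- Inf
  }
  params <- do.call(gbm_params, par_cfg)

  sch_cfg <- cfg$schedule %||% list()
  bad <- setdiff(names(sch_cfg), names(formals(make_schedule)))
  if (length(bad) > 0) {
    stop("unknown schedule key(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  schedule <- do.call(make_schedule, sch_cfg)

  dom_cfg <- cfg$domain %||% list()
  bad <- setdiff(names(dom_cfg),
                 c("shape", "seed", "b0", "h", "raster", "label_map"))
  if (length(bad) > 0) {
    stop("unknown domain key(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dom_defaults <- list(shape = c(127, 127), seed = 0, b0 = params$b0, h = 1)
  domain_options <- utils::modifyList(dom_defaults, dom_cfg)

  if (verbose) {
    defaulted <- setdiff(names(formals(gbm_params)), names(par_cfg))
    message("configuration loaded from ", path)
    if (length(defaulted) > 0) {
      vals <- vapply(defaulted, function(nm) {
        v <- params[[nm]]
        if (is.numeric(v)) format(v, digits = 6) else as.character(v)
      }, character(1))
      message("  defaulted parameters: ",
              paste0(defaulted, "=", vals, collapse = ", "))
    }
    message("  schedule: mode=", schedule$mode)
  }
  list(params = params, schedule = schedule, domain_options = domain_options)
}

#' Write a configuration file
#'
#' Inverse of [load_config()]: serialises a parameter set, schedule and
#' domain options to YAML (or JSON) such that reloading reproduces them.
#'
#' @param params A `gbm_params`.
#' @param schedule A `gbm_schedule`.
#' @param domain_options Named list of domain options.
#' @param path Output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, schedule, domain_options, path) {
  ser <- list(
    params = lapply(unclass(params), function(v) {
      if (is.numeric(v) && is.infinite(v)) "Inf" else v
    }),
    schedule = unclass(schedule),
    domain = domain_options
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(ser, path)
  } else if (ext == "json") {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  invisible(path)
}

build_domain_from_options <- function(opts) {
  if (!is.null(opts$raster)) {
    load_brain_slice(opts$raster, opts$label_map, b0 = opts$b0,
                     h = opts$h %||% 1)
  } else {
    synthetic_brain(shape = opts$shape, seed = opts$seed, b0 = opts$b0,
                    h = opts$h %||% 1)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
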