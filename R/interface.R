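# Configuration and provenance glue: a single human-editable YAML config
# with full defaults, converters into the typed spec objects, and run
# manifests sufficient to reproduce outputs exactly.

#' Default run configuration
#'
#' Nested list of every tunable the pipeline uses, with the documented
#' defaults. A config file only needs the fields that differ; the rest are
#' merged in from these defaults.
#'
#' @return Named nested list.
#' @export
default_run_config <- function() {
  list(
    road = list(length_m = 6000, lanes = 3, speed_limit_kmh = 90),
    sim = list(dt_s = 1, max_accel_ms2 = 2.6, max_decel_ms2 = 4.5,
               reaction_time_s = 1, driver_imperfection = 0.5,
               vehicle_length_m = 5, min_gap_m = 2.5,
               duration_s = 3600, warmup_s = 600),
    dffs = default_dffs_params(),
    grid = default_grid(),
    n_seeds = 30,
    master_seed = 1,
    power_model = list(exponent = 3),
    unsafe_threshold_kmh = 90,
    output_dir = "results",
    parallelism = 1
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read / write a run configuration
#'
#' YAML on disk; fields absent from the file take their documented defaults.
#' Reading validates the merged configuration and names the offending field
#' on failure. A write followed by a read is lossless.
#'
#' @param path File path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config file is not a YAML mapping")
  cfg <- merge_config(default_run_config(), user)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  need_pos <- list("road.length_m" = config$road$length_m,
                   "road.lanes" = config$road$lanes,
                   "road.speed_limit_kmh" = config$road$speed_limit_kmh,
                   "sim.dt_s" = config$sim$dt_s,
                   "sim.max_accel_ms2" = config$sim$max_accel_ms2,
                   "sim.max_decel_ms2" = config$sim$max_decel_ms2,
                   "sim.duration_s" = config$sim$duration_s,
                   "power_model.exponent" = config$power_model$exponent,
                   "n_seeds" = config$n_seeds)
  for (nm in names(need_pos)) {
    v <- need_pos[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop("invalid config field: ", nm, " must be a positive number")
  }
  si <- config$sim$driver_imperfection
  if (!is.numeric(si) || si < 0 || si > 1)
    stop("invalid config field: sim.driver_imperfection must lie in [0, 1]")
  if (!all(config$grid$sec_type %in% c("FIX1", "FIX2", "FIX3", "P2P")))
    stop("invalid config field: grid.sec_type")
  invisible(config)
}

#' Typed objects from a configuration
#'
#' @param config Configuration list (see [default_run_config()]).
#' @return `config_road()` a [road_spec()]; `config_sim_params()` a
#'   [sim_params()].
#' @export
config_road <- function(config) {
  road_spec(config$road$length_m, config$road$lanes,
            config$road$speed_limit_kmh)
}

#' @rdname config_road
#' @export
config_sim_params <- function(config) {
  s <- config$sim
  sim_params(s$dt_s, s$max_accel_ms2, s$max_decel_ms2, s$reaction_time_s,
             s$driver_imperfection, s$vehicle_length_m, s$min_gap_m,
             s$duration_s, s$warmup_s)
}

#' Write a run manifest
#'
#' Records the package version, the master seed and an MD5 digest of the
#' configuration (plus the configuration itself), which together suffice to
#' reproduce a run's outputs exactly.
#'
#' @param path Manifest path (YAML).
#' @param config Configuration list used for the run.
#' @param master_seed Master seed of the run.
#' @param overrides Optional named list of command-line/driver overrides
#'   applied on top of the config, recorded verbatim.
#' @export
write_manifest <- function(path, config, master_seed,
                           overrides = list()) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, tmp)
  digest <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "secsim",
    version = as.character(utils::packageVersion("secsim")),
    master_seed = master_seed,
    config_md5 = digest,
    overrides = overrides,
    config = config)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
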