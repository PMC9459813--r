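# Run configuration shared by the command-line interface: every numeric
# constant the pipeline uses lives in one serialisable structure, so any
# output can be traced back to the exact parameters that produced it.

#' Build, read and write a run configuration
#'
#' A `run_config` collects every tunable pipeline constant: the global
#' seed, the detector constants ([detector_config()]), windowing
#' parameters, step height, calibration offset and classifier grids. It
#' round-trips through YAML unchanged, and a short content hash is
#' embedded in every JSON output for provenance.
#'
#' @param seed Global integer seed.
#' @param detector A [detector_config()].
#' @param window_s,overlap Windowing parameters.
#' @param step_height Per-step staircase height in meters.
#' @param calibration_offset Additive power calibration in watts.
#' @param grids Classifier hyperparameter grids ([classifier_grids()]).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, detector = detector_config(), window_s = 1.5,
                       overlap = 0.5, step_height = 0.154,
                       calibration_offset = 0, grids = classifier_grids()) {
  structure(
    list(seed = as.integer(seed), detector = unclass(detector),
         window_s = window_s, overlap = overlap, step_height = step_height,
         calibration_offset = calibration_offset,
         grids = lapply(grids, as.data.frame)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg A `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("seed", "detector", "window_s", "overlap", "step_height",
            "calibration_offset")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("config schema violation: missing field(s) ", paste(missing, collapse = ", "))
  }
  det <- do.call(detector_config, raw$detector)
  grids <- if (!is.null(raw$grids)) {
    lapply(raw$grids, function(g) as.data.frame(lapply(g, unlist)))
  } else {
    classifier_grids()
  }
  run_config(seed = raw$seed, detector = det, window_s = raw$window_s,
             overlap = raw$overlap, step_height = raw$step_height,
             calibration_offset = raw$calibration_offset, grids = grids)
}

#' Short provenance hash of a configuration
#'
#' MD5 of the YAML serialisation, truncated to 12 hex characters; equal
#' configurations hash equally, so two runs with the same hash and inputs
#' produce identical outputs.
#' @param cfg A `run_config`.
#' @return A character scalar.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  substr(unname(tools::md5sum(tf)), 1, 12)
}

# provenance block embedded in CLI JSON outputs
provenance_block <- function(cfg) {
  list(config_hash = config_hash(cfg),
       package = "stairclimbr",
       version = as.character(utils::packageVersion("stairclimbr")))
}
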