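#' Pipeline configuration
#'
#' Collects every numeric constant used by the pipeline in one nested list.
#' Defaults are the operating point of the slip-detection protocol this
#' package implements: 150 Hz sampling, a 12 Hz fourth-order (effective)
#' zero-lag Butterworth filter, toe-off peaks of at least 0.13 m/s separated
#' by 90 frames with the event placed 5 frames after the peak, heel-off
#' anchor thresholds of 0.5 m/s^2 and 0.1 m/s, full-stop thresholds of
#' 0.5 m/s^2 and 0.01 m/s, 50 histogram bins with a 0.75 overlap cutoff for
#' feature selection, 10 under-sampling repeats and a C grid of
#' 0.01/0.1/1/10/100 for the linear SVMs.
#'
#' @param ... Named overrides. Nested values are addressed with a list, e.g.
#'   `pipeline_config(filter = list(cutoff_hz = 10))`. Unknown keys raise an
#'   error naming the offending key.
#'
#' @return A nested list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config(filter = list(cutoff_hz = 10))
#' cfg$filter$cutoff_hz
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sample_rate = 150,
    filter = list(
      cutoff_hz = 12,
      order = 4,              # effective order of the dual-pass filter
      order_per_pass = FALSE  # TRUE: design the full order per pass
    ),
    toe_off = list(
      peak_height = 0.13,     # m/s, minimum heel vertical velocity peak
      min_separation = 90,    # frames between retained peaks
      offset = 5,             # frames after the peak
      min_prominence = 0.02   # m/s, suppresses noise ripples
    ),
    heel_contact = list(
      trough_window_s = 0.08,   # sliding window for trough candidates
      height_frac = 0.35,       # heel height gate, fraction of trial range
      angle_band_deg = 25,      # gate: angle within offset + band
      angle_margin_deg = 2,     # gate: angle above offset - margin
      settle_velocity = 0.05,   # m/s; contact = descent slower than this
      min_prominence = 0.02
    ),
    direction_change = list(window_s = 0.5),
    anchors = list(accel_threshold = 0.5, vel_threshold = 0.1),
    full_stop = list(accel_threshold = 0.5, vel_threshold = 0.01),
    features = list(
      count_min_sep_ms_vertical = 100,  # peak-count features on vertical velocity
      count_min_sep_ms = 7,             # all other peak-count features
      min_prominence = 0.02,            # m/s noise floor for peaks/lobes
      planar_speed_floor = 0.05,        # m/s floor for AP+ML speed lobes
      zero_velocity_eps = 0.01          # m/s, "velocity reaches zero"
    ),
    selection = list(bins = 50, overlap_cutoff = 0.75),
    classifier = list(
      c_grid = c(0.01, 0.1, 1, 10, 100),
      repeats = 10,
      validation_fraction = 0.2,
      score = "platt"           # or "margin"
    ),
    matching = list(tolerance_frames = 15)
  )
  apply_overrides(defaults, list(...), path = "")
}

apply_overrides <- function(defaults, overrides, path) {
  if (length(overrides) == 0) {
    if (identical(path, "")) class(defaults) <- c("pipeline_config", "list")
    return(defaults)
  }
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("configuration overrides must be named (at '", path, "')")
  }
  for (nm in nms) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      stop("unknown configuration key: '", key, "'")
    }
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- apply_overrides(defaults[[nm]], overrides[[nm]], key)
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  if (identical(path, "")) class(defaults) <- c("pipeline_config", "list")
  defaults
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (inherits(config, "pipeline_config")) return(config)
  if (is.list(config)) return(do.call(pipeline_config, config))
  stop("`config` must be NULL, a pipeline_config, or a named list of overrides")
}
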