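#' Construct a marker trajectory series
#'
#' A `marker_series` holds the time-indexed 3-D positions of named foot
#' markers at a fixed sampling rate, plus trial metadata. Coordinates are in
#' metres with axis order AP (anterior-posterior, positive forward in the
#' participant-centric convention), ML (medial-lateral), and vertical
#' (surface-normal when the walkway is inclined). Frames are 0-based; the
#' time of frame `f` is `f / sample_rate` seconds.
#'
#' @param markers Named list of `n x 3` numeric matrices (columns AP, ML,
#'   vertical). All matrices must have the same number of rows. `NA` entries
#'   mark missing samples.
#' @param sample_rate Sampling rate in Hz (default 150).
#' @param slope_angle Walkway slope in degrees, within \[0, 15\].
#' @param direction_sign Walking direction along the lab AP axis (+1 / -1),
#'   or `NA` to infer it later from net heel displacement.
#' @param participant_id,trial_id Identifiers.
#'
#' @return An object of class `"marker_series"` with fields `markers`,
#'   `missing` (per-marker logical vector flagging frames with any missing
#'   coordinate), `sample_rate`, `slope_angle`, `direction_sign`,
#'   `participant_id`, `trial_id`.
#' @export
marker_series <- function(markers, sample_rate = 150, slope_angle = 0,
                          direction_sign = NA_real_,
                          participant_id = NA_character_,
                          trial_id = NA_character_) {
  if (!is.list(markers) || is.null(names(markers)) || any(names(markers) == "")) {
    stop("`markers` must be a named list of n x 3 matrices")
  }
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3) stop("each marker matrix must have 3 columns (AP, ML, vertical)")
    storage.mode(m) <- "double"
    colnames(m) <- c("ap", "ml", "vert")
    m
  })
  lens <- vapply(markers, nrow, integer(1))
  if (length(unique(lens)) != 1) {
    stop("inconsistent marker lengths: ", paste(lens, collapse = ", "))
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  if (slope_angle < 0 || slope_angle > 15) stop("slope_angle must be within [0, 15] degrees")
  out <- list(
    markers = markers,
    missing = lapply(markers, function(m) rowSums(is.na(m)) > 0),
    sample_rate = sample_rate,
    slope_angle = slope_angle,
    direction_sign = direction_sign,
    participant_id = participant_id,
    trial_id = trial_id
  )
  class(out) <- "marker_series"
  out
}

#' @export
print.marker_series <- function(x, ...) {
  n <- nrow(x$markers[[1]])
  cat(sprintf(
    "<marker_series> %d markers (%s), %d frames @ %g Hz (%.2f s), slope %g deg\n",
    length(x$markers), paste(names(x$markers), collapse = ", "),
    n, x$sample_rate, n / x$sample_rate, x$slope_angle
  ))
  miss <- sum(vapply(x$missing, sum, numeric(1)))
  if (miss > 0) cat(sprintf("  %d missing marker-frames\n", miss))
  invisible(x)
}

n_frames <- function(series) nrow(series$markers[[1]])

#' Identify the heel and toe markers of a series
#'
#' The heel marker is the one whose name contains "heel"; toe candidates
#' contain "toe". When several toe markers are present the designated toe is
#' the most anterior one (largest mean AP coordinate), unless named
#' explicitly.
#'
#' @param series A [marker_series()].
#' @param toe Optional explicit toe marker name.
#' @return List with elements `heel` and `toe` (marker names).
#' @export
foot_marker_roles <- function(series, toe = NULL) {
  nms <- names(series$markers)
  heel <- nms[grepl("heel", nms, ignore.case = TRUE)]
  if (length(heel) == 0) stop("no heel marker found: a marker named *heel* is required")
  toes <- nms[grepl("toe", nms, ignore.case = TRUE)]
  if (length(toes) == 0) stop("no toe marker found: a marker named *toe* is required")
  if (!is.null(toe)) {
    if (!toe %in% nms) stop("designated toe marker '", toe, "' not present")
    toes <- toe
  } else if (length(toes) > 1) {
    ap_mean <- vapply(toes, function(t) mean(series$markers[[t]][, "ap"], na.rm = TRUE),
                      numeric(1))
    toes <- toes[which.max(ap_mean)]
  }
  list(heel = heel[1], toe = toes[1])
}

#' Read marker trajectories
#'
#' Reads the package's CSV marker dialect: one header row
#' `frame,<marker>_x,<marker>_y,<marker>_z,...` with positions in metres and
#' axis order x = AP, y = ML, z = vertical. Empty cells or `NA` are flagged
#' as missing, never silently interpolated. Metadata (participant, trial,
#' slope, sampling rate, walking direction) can be supplied through a YAML
#' sidecar file.
#'
#' @param path Path to the trajectory file.
#' @param dialect `"csv"` (supported) or `"c3d"`.
#' @param metadata Optional path to a YAML key-value sidecar with any of
#'   `participant_id`, `trial_id`, `slope_angle`, `sample_rate`,
#'   `walking_direction` (+1/-1).
#' @param sample_rate Sampling rate in Hz, used when no sidecar provides one.
#' @return A [marker_series()].
#' @export
read_trajectories <- function(path, dialect = c("csv", "c3d"), metadata = NULL,
                              sample_rate = 150) {
  dialect <- match.arg(dialect)
  if (dialect == "c3d") {
    stop("C3D input is not supported by this build; export the trial to the ",
         "documented CSV dialect (frame,<marker>_x,<marker>_y,<marker>_z,...) ",
         "described in ?read_trajectories")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  cols <- setdiff(names(df), "frame")
  stems <- unique(sub("_[xyz]$", "", cols))
  markers <- list()
  for (s in stems) {
    need <- paste0(s, c("_x", "_y", "_z"))
    if (!all(need %in% cols)) {
      stop("marker '", s, "' is missing one of the _x/_y/_z columns")
    }
    markers[[s]] <- cbind(df[[need[1]]], df[[need[2]]], df[[need[3]]])
  }
  meta <- list(participant_id = NA_character_, trial_id = NA_character_,
               slope_angle = 0, sample_rate = sample_rate,
               walking_direction = NA_real_)
  if (!is.null(metadata)) {
    if (!file.exists(metadata)) stop("metadata file not found: ", metadata)
    meta <- modifyList(meta, yaml::read_yaml(metadata))
  }
  series <- marker_series(
    markers, sample_rate = meta$sample_rate, slope_angle = meta$slope_angle,
    direction_sign = as.numeric(meta$walking_direction),
    participant_id = as.character(meta$participant_id),
    trial_id = as.character(meta$trial_id)
  )
  foot_marker_roles(series)  # errors early if heel/toe are absent
  series
}

#' Write marker trajectories
#'
#' Writes the CSV dialect read by [read_trajectories()]. Missing samples are
#' written as `NA`.
#'
#' @param series A [marker_series()].
#' @param path Output path.
#' @param metadata Optional path for a YAML metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(series, path, metadata = NULL) {
  out <- data.frame(frame = seq_len(n_frames(series)) - 1L)
  for (nm in names(series$markers)) {
    m <- series$markers[[nm]]
    out[[paste0(nm, "_x")]] <- m[, "ap"]
    out[[paste0(nm, "_y")]] <- m[, "ml"]
    out[[paste0(nm, "_z")]] <- m[, "vert"]
  }
  write.csv(out, path, row.names = FALSE)
  if (!is.null(metadata)) {
    yaml::write_yaml(list(
      participant_id = series$participant_id, trial_id = series$trial_id,
      slope_angle = series$slope_angle, sample_rate = series$sample_rate,
      walking_direction = series$direction_sign
    ), metadata)
  }
  invisible(path)
}

#' Fill short interior gaps by linear interpolation
#'
#' Gaps of at most `max_gap` frames are linearly interpolated per coordinate;
#' longer gaps and gaps touching the sequence ends are left missing. The
#' missing mask is updated; non-missing samples are never altered.
#'
#' @param series A [marker_series()].
#' @param max_gap Maximum gap length (frames) to interpolate.
#' @return The series with gaps filled and an attribute `"unfilled"` giving
#'   the number of marker-frames still missing.
#' @export
fill_gaps <- function(series, max_gap = 10) {
  for (nm in names(series$markers)) {
    m <- series$markers[[nm]]
    for (j in seq_len(ncol(m))) {
      x <- m[, j]
      na <- is.na(x)
      if (!any(na)) next
      r <- rle(na)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in seq_along(r$lengths)) {
        if (!r$values[k]) next
        a <- starts[k]; b <- ends[k]
        interior <- a > 1 && b < length(x)
        if (interior && r$lengths[k] <= max_gap) {
          x[a:b] <- x[a - 1] + (x[b + 1] - x[a - 1]) * (seq_len(b - a + 1)) / (b - a + 2)
        }
      }
      m[, j] <- x
    }
    series$markers[[nm]] <- m
    series$missing[[nm]] <- rowSums(is.na(m)) > 0
  }
  attr(series, "unfilled") <- sum(vapply(series$missing, sum, numeric(1)))
  series
}

#' Express a series in the participant-centric frame
#'
#' Flips the AP axis if needed so that the participant's forward progress has
#' positive velocity; the vertical axis is unchanged. The direction is taken
#' from the series metadata, or inferred from the sign of the net heel AP
#' displacement over the bout. Applying the transform twice equals applying
#' it once.
#'
#' @param series A [marker_series()].
#' @param min_displacement Minimum net heel AP displacement (m) required to
#'   infer direction; below it the direction is ambiguous and an error is
#'   raised rather than guessing.
#' @return The transformed series, with `direction_sign = +1`.
#' @export
to_participant_frame <- function(series, min_displacement = 0.05) {
  sign_dir <- series$direction_sign
  if (is.null(sign_dir) || is.na(sign_dir)) {
    roles <- foot_marker_roles(series)
    ap <- series$markers[[roles$heel]][, "ap"]
    ap <- ap[!is.na(ap)]
    net <- ap[length(ap)] - ap[1]
    if (abs(net) < min_displacement) {
      stop("walking direction is ambiguous: net heel AP displacement ",
           sprintf("%.3f m", net), " is below ", min_displacement,
           " m; set `direction_sign` explicitly")
    }
    sign_dir <- sign(net)
  }
  if (sign_dir < 0) {
    series$markers <- lapply(series$markers, function(m) {
      m[, "ap"] <- -m[, "ap"]
      m
    })
  }
  series$direction_sign <- 1
  series
}
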