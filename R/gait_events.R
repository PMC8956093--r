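#' Detect toe-off events
#'
#' Toe-off is located from the heel vertical velocity: local maxima with
#' height at least 0.13 m/s and prominence above a small noise floor are
#' thinned so that retained peaks are at least 90 frames apart (greedy, by
#' descending height), and the toe-off event is placed five frames after
#' each retained peak.
#'
#' @param kin A [compute_foot_signals()] result.
#' @param config A [pipeline_config()] or list of overrides.
#' @return Integer vector of toe-off frames (1-based), possibly empty. The
#'   attribute `"peaks"` carries the underlying peak frames.
#' @export
detect_toe_off <- function(kin, config = NULL) {
  cfg <- as_config(config)
  hv <- kin$heel_vel[, "vert"]
  pk <- find_peaks(hv,
                   min_height = cfg$toe_off$peak_height,
                   min_separation = cfg$toe_off$min_separation,
                   min_prominence = cfg$toe_off$min_prominence)
  to <- pk$frame + cfg$toe_off$offset
  keep <- to <= length(hv)
  out <- as.integer(to[keep])
  attr(out, "peaks") <- as.integer(pk$frame[keep])
  out
}

#' Detect heel-contact events between consecutive toe-offs
#'
#' Candidate heel contacts are troughs of the heel vertical velocity found
#' in sliding 0.08-s windows between consecutive toe-offs. A candidate
#' survives if (i) the heel height at the trough is below 35% of the trial's
#' heel-height range, and (ii) the foot angle sits inside a band above the
#' flat-foot offset (the heel-first landing posture: toe up, heel down),
#' which rejects mid-swing toe-down troughs. Among survivors the earliest is
#' chosen, and the contact is placed at the first subsequent frame where the
#' heel's descent slows above a settle threshold (the descent has ended).
#' At most one contact is returned per toe-off interval.
#'
#' @param kin A [compute_foot_signals()] result.
#' @param toe_offs Toe-off frames from [detect_toe_off()].
#' @param config A [pipeline_config()] or list of overrides.
#' @return Integer vector of length `length(toe_offs) - 1`; element `i` is
#'   the heel contact between toe-offs `i` and `i + 1`, or `NA`.
#' @export
detect_heel_contact <- function(kin, toe_offs, config = NULL) {
  cfg <- as_config(config)
  if (length(toe_offs) < 2) return(integer(0))
  fs <- kin$sample_rate
  hv <- kin$heel_vel[, "vert"]
  hz <- kin$heel_pos[, "vert"]
  z_lo <- min(hz); z_rng <- max(hz) - z_lo
  flat <- flat_foot_offset(kin)
  sep <- max(1L, as.integer(round(cfg$heel_contact$trough_window_s * fs)))
  out <- rep(NA_integer_, length(toe_offs) - 1)
  for (i in seq_len(length(toe_offs) - 1)) {
    w <- (toe_offs[i] + 1L):(toe_offs[i + 1] - 1L)
    if (length(w) < 3) next
    tr <- find_peaks(-hv[w], min_separation = sep,
                     min_prominence = cfg$heel_contact$min_prominence)
    if (nrow(tr) == 0) next
    g <- w[tr$frame]
    ok <- hz[g] < z_lo + cfg$heel_contact$height_frac * z_rng &
      kin$foot_angle[g] > flat - cfg$heel_contact$angle_margin_deg &
      kin$foot_angle[g] < flat + cfg$heel_contact$angle_band_deg
    g <- g[ok]
    if (length(g) == 0) next
    g <- g[1]
    settle <- which(hv[g:max(w)] > -cfg$heel_contact$settle_velocity)
    hc <- if (length(settle) == 0) g else g + settle[1] - 1L
    out[i] <- as.integer(min(hc, max(w)))
  }
  out
}

# flat-foot angle offset: median foot angle while the foot is (nearly) still
flat_foot_offset <- function(kin) {
  speed <- sqrt(rowSums(kin$heel_vel^2)) + sqrt(rowSums(kin$toe_vel^2))
  still <- speed < 0.2
  if (sum(still) >= 10) median(kin$foot_angle[still]) else median(kin$foot_angle)
}

#' Assemble complete strides from detected events
#'
#' A complete stride requires the previous heel contact, this toe-off, this
#' heel contact and the next toe-off. Its boundaries follow the midpoint
#' rule: start = midpoint(previous heel contact, this toe-off); end =
#' midpoint(this heel contact, next toe-off). Strides overlapping a
#' direction change -- a sign reversal of the (already smoothed) heel AP
#' velocity sustained for more than 0.5 s -- are discarded, as are strides
#' with any missing event.
#'
#' @param kin A [compute_foot_signals()] result.
#' @param events List with `toe_offs` and `heel_contacts` as returned by
#'   [detect_toe_off()] and [detect_heel_contact()].
#' @param config A [pipeline_config()] or list of overrides.
#' @return data.frame with columns `stride_id`, `start`, `toe_off`,
#'   `heel_contact`, `end` (global 1-based frames), ordered in time.
#' @export
assemble_strides <- function(kin, events, config = NULL) {
  cfg <- as_config(config)
  to <- events$toe_offs
  hc <- events$heel_contacts
  empty <- data.frame(stride_id = integer(0), start = integer(0),
                      toe_off = integer(0), heel_contact = integer(0),
                      end = integer(0))
  if (length(to) < 3) return(empty)
  rev_frames <- direction_change_frames(kin$heel_vel[, "ap"],
                                        kin$sample_rate,
                                        cfg$direction_change$window_s)
  rows <- list()
  for (i in 2:(length(to) - 1)) {
    prev_hc <- hc[i - 1]; this_hc <- hc[i]
    if (is.na(prev_hc) || is.na(this_hc)) next
    start <- as.integer(round((prev_hc + to[i]) / 2))
    end <- as.integer(round((this_hc + to[i + 1]) / 2))
    if (!(start < to[i] && to[i] < this_hc && this_hc < end)) next
    if (any(rev_frames >= start & rev_frames <= end)) next
    rows[[length(rows) + 1]] <- data.frame(
      stride_id = i, start = start, toe_off = to[i],
      heel_contact = this_hc, end = end
    )
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$stride_id <- seq_len(nrow(out))
  out
}

# frames belonging to sustained (> window_s) negative runs of AP velocity
direction_change_frames <- function(v_ap, sample_rate, window_s) {
  neg <- v_ap < 0
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > window_s * sample_rate
  if (!any(keep)) return(integer(0))
  unlist(mapply(seq, starts[keep], ends[keep], SIMPLIFY = FALSE))
}

#' Bland-Altman agreement of event timings
#'
#' Pairs detected with reference events (nearest neighbour within a
#' tolerance, one-to-one, closest pairs first) and reports the mean paired
#' difference and the 95% limits of agreement (mean +/- 1.96 SD), all in
#' milliseconds. Unmatched events are excluded from the statistics and
#' reported separately.
#'
#' @param detected,reference Event frames (1-based).
#' @param sample_rate Sampling rate, Hz.
#' @param tolerance_frames Maximum |detected - reference| for a match.
#' @return List with `mean_error_ms`, `loa_low_ms`, `loa_high_ms`, `sd_ms`,
#'   `n_matched`, `n_unmatched_detected`, `n_unmatched_reference`,
#'   `differences_ms`.
#' @export
bland_altman_timing <- function(detected, reference, sample_rate = 150,
                                tolerance_frames = 15) {
  pairs <- expand.grid(d = seq_along(detected), r = seq_along(reference))
  if (nrow(pairs) > 0) {
    pairs$dist <- abs(detected[pairs$d] - reference[pairs$r])
    pairs <- pairs[pairs$dist <= tolerance_frames, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, pairs$r), , drop = FALSE]
  }
  used_d <- logical(length(detected)); used_r <- logical(length(reference))
  diffs <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    d <- pairs$d[k]; r <- pairs$r[k]
    if (used_d[d] || used_r[r]) next
    used_d[d] <- TRUE; used_r[r] <- TRUE
    diffs <- c(diffs, (detected[d] - reference[r]) / sample_rate * 1000)
  }
  m <- if (length(diffs)) mean(diffs) else NA_real_
  s <- if (length(diffs) > 1) sd(diffs) else 0
  list(
    mean_error_ms = m,
    loa_low_ms = if (length(diffs)) m - 1.96 * s else NA_real_,
    loa_high_ms = if (length(diffs)) m + 1.96 * s else NA_real_,
    sd_ms = s,
    n_matched = length(diffs),
    n_unmatched_detected = sum(!used_d),
    n_unmatched_reference = sum(!used_r),
    differences_ms = diffs
  )
}
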