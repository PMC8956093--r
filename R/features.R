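#' Curvature of a velocity signal at a frame
#'
#' Computes `kappa(t) = v''(t) / (1 + v'(t)^2)^(3/2)` with first and second
#' derivatives taken as central differences in per-frame units (no scaling
#' by the sampling rate), which keeps the statistic scale-stable at a fixed
#' sampling rate.
#'
#' @param v Numeric velocity signal.
#' @param t Frame (1-based); must be interior (`1 < t < length(v)`).
#' @return Curvature value at `t`.
#' @export
curvature <- function(v, t) {
  if (any(t <= 1 | t >= length(v))) {
    stop("curvature requires interior frames: 1 < t < ", length(v))
  }
  d1 <- (v[t + 1] - v[t - 1]) / 2
  d2 <- v[t + 1] - 2 * v[t] + v[t - 1]
  d2 / (1 + d1^2)^1.5
}

#' Locate the per-step anchor frames
#'
#' `T_heel_off` is the first frame before toe-off (searching from the stride
#' start) at which the heel AP acceleration reaches 0.5 m/s^2 while the heel
#' AP velocity is still below 0.1 m/s -- the instant the heel starts moving
#' for push-off. `T_max_velocity` is the frame of maximum heel AP velocity
#' within the stride (earliest frame on ties). Either anchor can be absent;
#' features that depend on an absent anchor take documented defaults.
#'
#' @param kin A [compute_foot_signals()] result.
#' @param stride One-row stride data.frame (`start`, `toe_off`,
#'   `heel_contact`, `end`), as produced by [assemble_strides()].
#' @param config A [pipeline_config()] or list of overrides.
#' @return List with `t_heel_off` (frame or `NA`) and `t_max_velocity`.
#' @export
find_anchors <- function(kin, stride, config = NULL) {
  cfg <- as_config(config)
  ha <- kin$heel_vel[, "ap"]
  acc <- kin$heel_acc_ap
  pre <- stride$start:(stride$toe_off - 1L)
  hit <- pre[acc[pre] >= cfg$anchors$accel_threshold &
               ha[pre] < cfg$anchors$vel_threshold]
  t_ho <- if (length(hit)) hit[1] else NA_integer_
  seg <- stride$start:stride$end
  t_mv <- seg[which.max(ha[seg])]
  list(t_heel_off = t_ho, t_max_velocity = t_mv)
}

feature_ids <- function() 1:36

#' Feature subsets used by the two classifiers
#'
#' The toe-slip classifier uses the features marked for it in the feature
#' catalogue (see [feature_catalogue()]); likewise the heel-slip classifier.
#'
#' @param taxonomy `"toe"` or `"heel"`.
#' @return Integer vector of feature ids.
#' @export
selected_features <- function(taxonomy = c("toe", "heel")) {
  taxonomy <- match.arg(taxonomy)
  if (taxonomy == "toe") {
    c(3, 4, 5, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24,
      26, 27, 28, 29, 33, 34, 35)
  } else {
    c(5, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 24, 25, 30, 33, 34, 36)
  }
}

#' Catalogue of the 36 per-step features
#'
#' @return data.frame with `feature_id`, `description`, `toe_selected`,
#'   `heel_selected`.
#' @export
feature_catalogue <- function() {
  desc <- c(
    "Number of negative peaks separated by 100 ms in heel vertical velocity",
    "Number of positive peaks separated by 100 ms in heel vertical velocity",
    "Number of positive peaks separated by 7 ms in toe vertical velocity between toe off and heel contact",
    "Difference of the number of positive and negative peaks separated by 7 ms in toe vertical velocity between toe off and heel contact",
    "Heel AP velocity at heel contact",
    "Time for heel AP velocity to reach zero after heel contact",
    "Area of the heel AP velocity from heel contact to the point where velocity reaches zero",
    "Area of the negative peak in heel AP velocity immediately after heel contact",
    "Area of the negative peak in heel AP velocity after heel contact different from feature 8",
    "AP displacement of the heel between heel contact and mid-stance",
    "Number of positive peaks in heel AP velocity after heel contact",
    "Velocity of the largest positive peak in heel AP velocity after heel contact",
    "Area of positive peaks in heel AP velocity after heel contact",
    "Area of positive peaks in heel AP and medial-lateral velocity after heel contact",
    "Sum of features 7 and 10",
    "Difference between features 13 and 8",
    "Binary: foot comes to a full stop after heel contact (|acc| < 0.5 m/s^2 and |vel| < 0.01 m/s)",
    "Number of positive peaks in heel vertical velocity before toe off",
    "Number of positive peaks in toe vertical velocity before toe off",
    "Number of positive peaks in heel AP velocity before toe off",
    "Number of positive peaks in toe AP velocity before toe off",
    "Maximum velocity of the largest positive peak in heel AP velocity before toe off",
    "Maximum velocity of the largest positive peak in toe AP velocity before toe off",
    "Heel AP velocity at T_heel_off",
    "Toe AP velocity at T_heel_off",
    "Number of negative peaks in toe AP velocity before toe off",
    "Width of the largest negative peak in toe AP velocity before toe off",
    "Maximum velocity of the largest negative peak in toe AP velocity before toe off",
    "Area of all negative peaks in toe AP velocity before toe off",
    "Number of positive peaks in heel AP velocity after T_max_velocity",
    "Sum of curvature values between T_heel_off and T_max_velocity",
    "Mean of curvature values between T_heel_off and T_max_velocity",
    "Sum of curvature values between T_max_velocity and the next step's T_heel_off",
    "Mean of curvature values between T_max_velocity and the next step's T_heel_off",
    "Chord-to-curve area of heel AP velocity from the zero before T_max_velocity to T_max_velocity",
    "Chord-to-curve area of heel AP velocity from T_max_velocity to the zero after it"
  )
  data.frame(
    feature_id = feature_ids(),
    description = desc,
    toe_selected = feature_ids() %in% selected_features("toe"),
    heel_selected = feature_ids() %in% selected_features("heel")
  )
}

#' Compute the 36-feature vector for one stride
#'
#' Evaluates every feature of the catalogue on one stride. Windows are:
#' "before toe off" = stride start to the frame before toe-off; "between toe
#' off and heel contact" = toe-off to heel contact; "after heel contact" =
#' the frame after heel contact to the stride end. Degenerate inputs (absent
#' anchors, no qualifying peaks) produce defined defaults -- counts, areas,
#' velocities and curvature sums of 0 -- and the per-feature validity mask
#' records which values came from defaults.
#'
#' @param kin A [compute_foot_signals()] result (global signals).
#' @param stride One-row stride data.frame.
#' @param next_t_heel_off The next stride's `T_heel_off` (global frame), or
#'   `NA` when unavailable; used by features 33 and 34.
#' @param config A [pipeline_config()] or list of overrides.
#' @return List with `values` (named numeric vector `f1`..`f36`), `valid`
#'   (logical mask), and `anchors`.
#' @export
compute_feature_vector <- function(kin, stride, next_t_heel_off = NA,
                                   config = NULL) {
  cfg <- as_config(config)
  fs <- kin$sample_rate
  fcfg <- cfg$features
  ha <- kin$heel_vel[, "ap"]; ta <- kin$toe_vel[, "ap"]
  hv <- kin$heel_vel[, "vert"]; tv <- kin$toe_vel[, "vert"]
  hm <- kin$heel_vel[, "ml"]
  acc <- kin$heel_acc_ap
  hx <- kin$heel_pos[, "ap"]
  s <- stride$start; to <- stride$toe_off; hc <- stride$heel_contact; e <- stride$end
  w_all <- s:e
  w_pre <- s:(to - 1L)
  w_sw <- to:hc
  w_post <- (hc + 1L):e

  anch <- find_anchors(kin, stride, cfg)
  t_ho <- anch$t_heel_off; t_mv <- anch$t_max_velocity

  val <- setNames(numeric(36), paste0("f", 1:36))
  ok <- setNames(rep(TRUE, 36), paste0("f", 1:36))

  inv <- function(sig, win, pol, sep_ms = fcfg$count_min_sep_ms) {
    peak_inventory(sig, fs, win, pol, min_separation_ms = sep_ms,
                   min_prominence = fcfg$min_prominence)
  }
  lobe_area_sum <- function(p) if (nrow(p) == 0) 0 else sum(p$area[!duplicated(p$lobe_id)])

  # 1-2: peak counts in heel vertical velocity over the whole step
  val["f1"] <- nrow(inv(hv, w_all, "negative", fcfg$count_min_sep_ms_vertical))
  val["f2"] <- nrow(inv(hv, w_all, "positive", fcfg$count_min_sep_ms_vertical))
  # 3-4: toe vertical velocity peaks during swing
  p3 <- inv(tv, w_sw, "positive")
  n3 <- nrow(p3); n4 <- nrow(inv(tv, w_sw, "negative"))
  val["f3"] <- n3
  val["f4"] <- n3 - n4
  # 5: heel AP velocity at heel contact
  val["f5"] <- ha[hc]
  # 6-7: time and area until the heel AP velocity reaches zero after contact
  eps <- fcfg$zero_velocity_eps
  if (abs(ha[hc]) <= eps) {
    t_zero <- hc
  } else {
    post <- hc:e
    z <- post[abs(ha[post]) <= eps | sign(ha[post]) != sign(ha[hc])]
    t_zero <- if (length(z)) z[1] else { ok["f6"] <- ok["f7"] <- FALSE; e }
  }
  val["f6"] <- (t_zero - hc) / fs
  val["f7"] <- trapz_range(ha, hc, t_zero, fs)
  # 8-9: negative lobes of heel AP velocity after contact
  p_neg_post <- inv(ha, w_post, "negative")
  if (nrow(p_neg_post) > 0) {
    lobes <- p_neg_post[!duplicated(p_neg_post$lobe_id), , drop = FALSE]
    val["f8"] <- lobes$area[1]
    rest <- lobes[-1, , drop = FALSE]
    val["f9"] <- if (nrow(rest)) max(rest$area) else 0
  } else ok["f8"] <- ok["f9"] <- FALSE
  # 10: heel AP displacement from contact to mid-stance (minimum foot speed)
  speed <- sqrt(rowSums(kin$heel_vel^2)) + sqrt(rowSums(kin$toe_vel^2))
  mid_stance <- w_post[which.min(speed[w_post])]
  val["f10"] <- hx[mid_stance] - hx[hc]
  # 11-13: positive lobes of heel AP velocity after contact
  p_pos_post <- inv(ha, w_post, "positive")
  val["f11"] <- nrow(p_pos_post)
  val["f12"] <- if (nrow(p_pos_post)) max(p_pos_post$height) else 0
  val["f13"] <- lobe_area_sum(p_pos_post)
  # 14: planar (AP + ML) heel speed lobes after contact
  sp <- sqrt(ha^2 + hm^2)
  p14 <- peak_inventory(sp - fcfg$planar_speed_floor, fs, w_post, "positive",
                        min_separation_ms = fcfg$count_min_sep_ms,
                        min_prominence = fcfg$min_prominence)
  val["f14"] <- lobe_area_sum(p14)
  # 15-16: composites
  val["f15"] <- val["f7"] + val["f10"]
  val["f16"] <- val["f13"] - val["f8"]
  # 17: full stop after heel contact
  val["f17"] <- as.numeric(any(
    abs(acc[w_post]) < cfg$full_stop$accel_threshold &
      abs(ha[w_post]) < cfg$full_stop$vel_threshold
  ))
  # 18-23: peak counts/heights before toe-off
  val["f18"] <- nrow(inv(hv, w_pre, "positive"))
  val["f19"] <- nrow(inv(tv, w_pre, "positive"))
  p20 <- inv(ha, w_pre, "positive")
  p21 <- inv(ta, w_pre, "positive")
  val["f20"] <- nrow(p20)
  val["f21"] <- nrow(p21)
  val["f22"] <- if (nrow(p20)) max(p20$height) else 0
  val["f23"] <- if (nrow(p21)) max(p21$height) else 0
  # 24-25: AP velocities at T_heel_off
  if (!is.na(t_ho)) {
    val["f24"] <- ha[t_ho]
    val["f25"] <- ta[t_ho]
  } else ok["f24"] <- ok["f25"] <- FALSE
  # 26-29: negative toe AP lobes before toe-off
  p26 <- inv(ta, w_pre, "negative")
  val["f26"] <- nrow(p26)
  if (nrow(p26) > 0) {
    big <- which.min(p26$height)
    val["f27"] <- p26$width_s[big]
    val["f28"] <- p26$height[big]
    val["f29"] <- lobe_area_sum(p26)
  }
  # 30: positive heel AP peaks after T_max_velocity
  if (t_mv < e) val["f30"] <- nrow(inv(ha, (t_mv + 1L):e, "positive"))
  # 31-34: curvature sums/means between anchors
  kappa_sum <- function(a, b) {
    lo <- max(a, 2L); hi <- min(b, length(ha) - 1L)
    if (lo > hi) 0 else sum(curvature(ha, seq.int(lo, hi)))
  }
  if (!is.na(t_ho) && t_ho < t_mv) {
    val["f31"] <- kappa_sum(t_ho, t_mv)
    val["f32"] <- val["f31"] / (t_mv - t_ho)
  } else ok["f31"] <- ok["f32"] <- FALSE
  if (!is.na(next_t_heel_off) && next_t_heel_off > t_mv) {
    val["f33"] <- kappa_sum(t_mv, next_t_heel_off)
    val["f34"] <- val["f33"] / (next_t_heel_off - t_mv)
  } else ok["f33"] <- ok["f34"] <- FALSE
  # 35-36: chord-to-curve areas around T_max_velocity
  pre_mv <- s:t_mv
  z0 <- pre_mv[ha[pre_mv] <= 0]
  z0 <- if (length(z0)) max(z0) else s
  val["f35"] <- chord_area(ha, z0, t_mv, fs)
  post_mv <- t_mv:e
  z1 <- post_mv[ha[post_mv] <= 0]
  z1 <- if (length(z1)) min(z1) else e
  val["f36"] <- chord_area(ha, t_mv, z1, fs)

  list(values = val, valid = ok,
       anchors = list(t_heel_off = t_ho, t_max_velocity = t_mv))
}

# signed area between the curve x[a..b] and the straight chord joining
# (a, x[a]) and (b, x[b])
chord_area <- function(x, a, b, sample_rate) {
  if (b <= a) return(0)
  trapz_range(x, a, b, sample_rate) -
    (x[a] + x[b]) / 2 * (b - a) / sample_rate
}

#' Compute features for every stride of a trial
#'
#' Runs [compute_feature_vector()] on each stride, wiring each stride's
#' features 33/34 to the following stride's `T_heel_off`.
#'
#' @param kin A [compute_foot_signals()] result.
#' @param strides Stride data.frame from [assemble_strides()] (or with
#'   perturbed events for sensitivity analyses).
#' @param config A [pipeline_config()] or list of overrides.
#' @return data.frame with `stride_id`, event columns, `t_heel_off`,
#'   `t_max_velocity` and `f1`..`f36`; attribute `"valid"` holds the
#'   logical validity mask (strides x features).
#' @export
compute_features <- function(kin, strides, config = NULL) {
  cfg <- as_config(config)
  n <- nrow(strides)
  if (n == 0) {
    out <- cbind(strides,
                 as.data.frame(matrix(numeric(0), 0, 38,
                                      dimnames = list(NULL, c("t_heel_off", "t_max_velocity",
                                                              paste0("f", 1:36))))))
    attr(out, "valid") <- matrix(TRUE, 0, 36)
    return(out)
  }
  anchors <- lapply(seq_len(n), function(i) find_anchors(kin, strides[i, ], cfg))
  t_ho_all <- vapply(anchors, function(a) as.numeric(a$t_heel_off), numeric(1))
  vals <- matrix(0, n, 36, dimnames = list(NULL, paste0("f", 1:36)))
  valid <- matrix(TRUE, n, 36, dimnames = list(NULL, paste0("f", 1:36)))
  t_mv_all <- numeric(n)
  for (i in seq_len(n)) {
    nxt <- if (i < n) t_ho_all[i + 1] else NA
    fv <- compute_feature_vector(kin, strides[i, ], next_t_heel_off = nxt,
                                 config = cfg)
    vals[i, ] <- fv$values
    valid[i, ] <- fv$valid
    t_mv_all[i] <- fv$anchors$t_max_velocity
  }
  out <- cbind(strides, t_heel_off = t_ho_all, t_max_velocity = t_mv_all,
               as.data.frame(vals))
  attr(out, "valid") <- valid
  out
}

#' Histogram-overlap feature selection
#'
#' For each feature, class-conditional histograms are built on the pooled
#' min-max range with a fixed number of bins and normalised to the class
#' population; the overlap of a class pair is the sum over bins of the
#' pointwise minimum. A feature is discarded when every pairwise overlap is
#' at or above the cutoff (default 0.75).
#'
#' @param features data.frame or matrix of feature values (columns
#'   `f1`..`f36` or any numeric columns).
#' @param labels Class label per row (factor or character).
#' @param bins Number of histogram bins (default 50).
#' @param overlap_cutoff Discard threshold (default 0.75).
#' @return List of class `"feature_selection"`: `pairwise` (data.frame with
#'   `feature`, `class_a`, `class_b`, `overlap`), `summary` (`feature`,
#'   `max_overlap`, `min_overlap`, `kept`), `kept` (feature names),
#'   `skipped_pairs`, `bins`.
#' @export
histogram_overlap_selection <- function(features, labels, bins = 50,
                                        overlap_cutoff = 0.75) {
  if (bins < 2) stop("bins must be >= 2")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("at least 2 classes are required")
  labels <- droplevels(labels)
  feat_cols <- colnames(features)
  cls <- levels(labels)
  counts <- table(labels)
  pairs_idx <- utils::combn(cls, 2)
  pw <- list(); skipped <- list()
  for (fc in feat_cols) {
    x <- as.numeric(features[[fc]])
    rng <- range(x, finite = TRUE)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    hist_by_class <- lapply(cls, function(cl) {
      xi <- x[labels == cl]
      h <- hist(pmin(pmax(xi, rng[1]), rng[2]), breaks = brk, plot = FALSE)
      h$counts / max(1, length(xi))
    })
    names(hist_by_class) <- cls
    for (k in seq_len(ncol(pairs_idx))) {
      a <- pairs_idx[1, k]; b <- pairs_idx[2, k]
      if (counts[a] < 2 || counts[b] < 2) {
        skipped[[length(skipped) + 1]] <- data.frame(feature = fc, class_a = a, class_b = b)
        next
      }
      ov <- sum(pmin(hist_by_class[[a]], hist_by_class[[b]]))
      pw[[length(pw) + 1]] <- data.frame(feature = fc, class_a = a,
                                         class_b = b, overlap = ov)
    }
  }
  pw <- do.call(rbind, pw)
  summ <- do.call(rbind, lapply(feat_cols, function(fc) {
    o <- pw$overlap[pw$feature == fc]
    if (length(o) == 0) {
      data.frame(feature = fc, max_overlap = NA_real_, min_overlap = NA_real_,
                 kept = TRUE)
    } else {
      data.frame(feature = fc, max_overlap = max(o), min_overlap = min(o),
                 kept = !all(o >= overlap_cutoff))
    }
  }))
  out <- list(pairwise = pw, summary = summ,
              kept = summ$feature[summ$kept],
              skipped_pairs = if (length(skipped)) do.call(rbind, skipped) else NULL,
              bins = bins, overlap_cutoff = overlap_cutoff)
  class(out) <- "feature_selection"
  out
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d features, %d kept (bins = %d, cutoff = %g)\n",
              nrow(x$summary), sum(x$summary$kept), x$bins, x$overlap_cutoff))
  invisible(x)
}

#' Long-format export of a feature table
#'
#' @param features Result of [compute_features()].
#' @return data.frame with `stride_id`, `feature_id`, `value`, `valid`.
#' @export
feature_table_long <- function(features) {
  valid <- attr(features, "valid")
  rows <- lapply(seq_len(nrow(features)), function(i) {
    data.frame(stride_id = features$stride_id[i], feature_id = 1:36,
               value = as.numeric(features[i, paste0("f", 1:36)]),
               valid = as.logical(valid[i, ]))
  })
  do.call(rbind, rows)
}
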