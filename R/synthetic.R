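SLIP_CLASSES <- c("normal", "BTS", "FTS", "BHS", "FHS", "FHS_variant")

# Template geometry (frames relative to the nominal toe-off T of each cycle,
# at 150 Hz; scaled linearly for other rates). Heel vertical velocity: a
# positive rise lobe peaking 5 frames before toe-off (so the operational
# toe-off, peak + 5, is T itself), a mid-swing descent lobe and a short
# final descent lobe ending at heel contact T + 58. AP velocity: one
# raised-cosine swing bell per marker whose area is the step length. All
# lobes are raised cosines, so displacement integrals are analytic.
TEMPLATE <- list(
  rise = list(start = -20, dur = 30, area = 0.12),
  desc1 = list(start = 18, dur = 20, area = -0.09),
  desc2 = list(start = 40, dur = 18, area = -0.03),
  heel_bell = list(start = -10, dur = 68),
  toe_bell = list(start = -2, dur = 60),
  toe_up = list(start = 0, dur = 22, area = 0.05),
  toe_down = list(start = 53, dur = 25, area = -0.05),
  hc_offset = 58,
  marker_gap_ap = 0.248,   # heel-to-toe marker AP separation, m
  toe_marker_height = 0.03 # toe marker height above the sole, m
)

# add a raised-cosine velocity lobe: duration dur frames, signed area in m
add_lobe <- function(v, start, dur, area, fs) {
  if (dur < 2) return(v)
  idx <- start + 0:dur
  ok <- idx >= 1 & idx <= length(v)
  u <- (0:dur)[ok] / dur
  v[idx[ok]] <- v[idx[ok]] + (2 * area / (dur / fs)) * 0.5 * (1 - cos(2 * pi * u))
  v
}

cumtrapz <- function(v, fs) c(0, cumsum((v[-1] + v[-length(v)]) / 2)) / fs

default_slip_distance <- function(class) {
  switch(class,
         normal = 0,
         BTS = runif(1, 0.015, 0.065),
         FTS = runif(1, 0.008, 0.030),
         BHS = runif(1, 0.005, 0.015),
         FHS = runif(1, 0.015, 0.065),
         FHS_variant = runif(1, 0.020, 0.060))
}

# Build one continuous bout from a per-step class table.
# steps: data.frame with toe_class (none/BTS/FTS), heel_class
# (none/BHS/FHS/FHS_variant... stored as BHS/FHS + variant flag), d_toe,
# d_heel, variant (logical)
synth_bout <- function(steps, fs = 150, cadence = 100, step_length = 0.9,
                       z_amp = 1, step_jitter = 0.04, noise_sd = 5e-4,
                       direction_sign = 1, lead = 80, tail = 130) {
  n <- nrow(steps)
  stride <- round(fs * 120 / cadence)
  sc <- fs / 150  # frame-offset scale for non-150 Hz rates
  off <- function(x) as.integer(round(x * sc))
  tos <- lead + cumsum(c(0, round(stride * (1 + rnorm(n - 1, 0, 0.4 * step_jitter)))))
  N <- tos[n] + tail
  vz_h <- vz_t <- va_h <- va_t <- vm <- numeric(N)
  tmpl <- TEMPLATE
  hc_truth <- integer(n); peak_truth <- integer(n)

  for (k in seq_len(n)) {
    T0 <- tos[k]
    j <- function() 1 + rnorm(1, 0, step_jitter)
    L <- step_length * j()
    toe_slip <- steps$toe_class[k] != "none"
    heel_slip <- steps$heel_class[k] != "none"
    rippled <- isTRUE(steps$ripple[k])
    rise_area <- tmpl$rise$area * z_amp * j()
    ripple_z <- if (rippled) 0.012 * z_amp else 0
    ripple_t <- if (rippled) 0.006 * z_amp else 0
    # heel vertical: rise + ripple, then two descents returning exactly to 0
    vz_h <- add_lobe(vz_h, T0 + off(tmpl$rise$start), off(tmpl$rise$dur), rise_area, fs)
    if (ripple_z > 0) vz_h <- add_lobe(vz_h, T0 - off(32), off(14), ripple_z, fs)
    d1 <- tmpl$desc1$area / (tmpl$rise$area) * (rise_area) - ripple_z
    d2 <- tmpl$desc2$area / (tmpl$rise$area) * (rise_area)
    vz_h <- add_lobe(vz_h, T0 + off(tmpl$desc1$start), off(tmpl$desc1$dur), d1, fs)
    vz_h <- add_lobe(vz_h, T0 + off(tmpl$desc2$start), off(tmpl$desc2$dur), d2, fs)
    # toe vertical: up, (slip ripples), down closing the budget
    up_area <- tmpl$toe_up$area * z_amp * j()
    vz_t <- add_lobe(vz_t, T0 + off(tmpl$toe_up$start), off(tmpl$toe_up$dur), up_area, fs)
    extra_t <- 0
    if (rippled) {
      vz_t <- add_lobe(vz_t, T0 - off(32), off(14), ripple_t, fs)      # f19
      vz_t <- add_lobe(vz_t, T0 + off(28), off(14), 0.008 * z_amp, fs) # f3/f4
      extra_t <- ripple_t + 0.008 * z_amp
    }
    vz_t <- add_lobe(vz_t, T0 + off(tmpl$toe_down$start), off(tmpl$toe_down$dur),
                     -(up_area + extra_t), fs)
    # AP swing bells (equal displacement for both markers)
    va_h <- add_lobe(va_h, T0 + off(tmpl$heel_bell$start), off(tmpl$heel_bell$dur), L, fs)
    va_t <- add_lobe(va_t, T0 + off(tmpl$toe_bell$start), off(tmpl$toe_bell$dur), L, fs)
    hc <- T0 + off(tmpl$hc_offset)
    hc_truth[k] <- hc
    peak_truth[k] <- T0 + off(tmpl$rise$start) + off(tmpl$rise$dur) %/% 2

    # toe-slip perturbations: AP lobe (rigid foot: both markers) before TO
    if (toe_slip) {
      d <- steps$d_toe[k] * sign_of_toe(steps$toe_class[k])
      va_h <- add_lobe(va_h, T0 - off(35), off(23), d, fs)
      va_t <- add_lobe(va_t, T0 - off(35), off(23), d, fs)
      vm <- add_lobe(vm, T0 - off(35), off(23), 0.3 * abs(d) * sample(c(-1, 1), 1), fs)
    }
    # sub-slip gait variability: a small AP excursion before toe-off that is
    # not a slip in the ground truth (the ambiguity zone human observers
    # struggle with for small forward toe slips / abnormal push-offs)
    if (steps$shuffle_d[k] != 0) {
      va_h <- add_lobe(va_h, T0 - off(35), off(23), steps$shuffle_d[k], fs)
      va_t <- add_lobe(va_t, T0 - off(35), off(23), steps$shuffle_d[k], fs)
    }
    # heel-slip perturbations: AP lobe around/after HC + residual oscillation
    if (heel_slip) {
      if (steps$variant[k]) {
        # elevated AP velocity at contact, monotone decay, no post-HC maximum
        va_h <- add_lobe(va_h, hc - off(18), off(36), 2 * steps$d_heel[k], fs)
        va_t <- add_lobe(va_t, hc - off(18), off(36), 2 * steps$d_heel[k], fs)
      } else {
        d <- steps$d_heel[k] * sign_of_heel(steps$heel_class[k])
        va_h <- add_lobe(va_h, hc - off(2), off(26), d, fs)
        va_t <- add_lobe(va_t, hc - off(2), off(26), d, fs)
      }
      vm <- add_lobe(vm, hc - off(4), off(26),
                     0.3 * steps$d_heel[k] * sample(c(-1, 1), 1), fs)
      # residual micro-motion after an abrupt slip: defeats the post-contact
      # full-stop criterion throughout the stance half that belongs to this
      # stride. The variant decays smoothly by definition, so it keeps the
      # normal-step stillness (and is the harder class for it).
      if (isTRUE(steps$osc[k])) {
        next_to <- if (k < n) tos[k + 1] else tos[k] + stride
        half_period <- max(2L, as.integer(round(fs / 10)))  # 5 Hz motion
        len <- (hc + next_to) %/% 2 + 6 - (hc + off(16))
        len <- half_period * ceiling(len / half_period)
        osc <- hc + off(16) + 0:len
        osc <- osc[osc <= N]
        va_h[osc] <- va_h[osc] + 0.07 * sin(pi * (osc - osc[1]) / half_period)
      }
    }
  }

  t_idx <- seq_len(N)
  heel <- cbind(ap = cumtrapz(va_h, fs),
                ml = 0.01 * sin(2 * pi * t_idx / stride) + cumtrapz(vm, fs),
                vert = cumtrapz(vz_h, fs))
  toe <- cbind(ap = cumtrapz(va_t, fs) + tmpl$marker_gap_ap,
               ml = 0.01 * sin(2 * pi * t_idx / stride) + cumtrapz(vm, fs),
               vert = cumtrapz(vz_t, fs) + tmpl$toe_marker_height)
  if (noise_sd > 0) {
    heel <- heel + matrix(rnorm(3 * N, 0, noise_sd), N, 3)
    toe <- toe + matrix(rnorm(3 * N, 0, noise_sd), N, 3)
  }
  if (direction_sign < 0) {
    heel[, "ap"] <- -heel[, "ap"]
    toe[, "ap"] <- -toe[, "ap"]
  }
  truth <- data.frame(
    step = seq_len(n),
    to_truth = as.integer(tos),
    hc_truth = hc_truth,
    peak_truth = peak_truth,
    toe_class = ifelse(steps$toe_class == "none", "NTS", steps$toe_class),
    heel_class = ifelse(steps$heel_class == "none", "NHS",
                        ifelse(steps$variant, "FHS", steps$heel_class)),
    slip_distance = pmax(steps$d_toe, steps$d_heel),
    variant = steps$variant
  )
  truth$slip <- slip_flag(truth$toe_class, truth$heel_class)
  list(heel = heel, toe = toe, truth = truth)
}

sign_of_toe <- function(cl) if (cl == "BTS") -1 else 1
sign_of_heel <- function(cl) if (cl == "BHS") -1 else 1

archetype_steps <- function(class, slip_distance) {
  toe <- if (class %in% c("BTS", "FTS")) class else "none"
  heel <- if (class %in% c("BHS", "FHS")) class else if (class == "FHS_variant") "FHS" else "none"
  data.frame(toe_class = toe,
             heel_class = if (class == "FHS_variant") "FHS" else heel,
             d_toe = if (toe == "none") 0 else slip_distance,
             d_heel = if (heel == "none" && class != "FHS_variant") 0 else slip_distance,
             variant = class == "FHS_variant",
             ripple = FALSE,
             osc = FALSE,
             shuffle_d = 0)
}

#' Generate one synthetic step
#'
#' Builds a short walking bout containing a single step of the requested
#' morphology, flanked by lead-in and lead-out stance so the stride is
#' complete. The six morphologies are: a normal step and five slip types --
#' backward/forward toe slip (an AP velocity excursion of the foot before
#' toe-off), backward/forward heel slip (an excursion after heel contact)
#' and the forward-heel-slip variant (elevated AP heel velocity at contact
#' decaying monotonically, with no post-contact local maximum). The
#' displacement integral of the slip excursion equals `slip_distance`.
#'
#' @param class One of `"normal"`, `"BTS"`, `"FTS"`, `"BHS"`, `"FHS"`,
#'   `"FHS_variant"`.
#' @param slip_distance Slip distance in metres (must be 0 for a normal
#'   step, > 0 otherwise; `NULL` draws a class-typical value).
#' @param slope Walkway slope, degrees.
#' @param cadence Steps per minute.
#' @param noise_sd Marker position noise SD in metres (0 = noiseless).
#' @param sample_rate Hz.
#' @param seed RNG seed.
#' @return List with `series` (a [marker_series()]) and `truth` (one-row
#'   data.frame: `to_truth`, `hc_truth`, `peak_truth`, `toe_class`,
#'   `heel_class`, `slip`, `slip_distance`).
#' @export
generate_step <- function(class = "normal", slip_distance = NULL, slope = 0,
                          cadence = 100, noise_sd = 5e-4, sample_rate = 150,
                          seed = 1) {
  class <- match.arg(class, SLIP_CLASSES)
  old <- local_seed(seed); on.exit(restore_seed(old))
  if (is.null(slip_distance)) slip_distance <- default_slip_distance(class)
  if (slip_distance < 0) stop("slip_distance must be >= 0")
  if (class == "normal" && slip_distance != 0) {
    stop("a normal step must have slip_distance 0")
  }
  if (class != "normal" && slip_distance == 0) {
    stop("a slip step must have slip_distance > 0")
  }
  steps <- archetype_steps(class, slip_distance)
  # pad with a normal step on each side so the middle stride is complete
  pad <- archetype_steps("normal", 0)
  b <- synth_bout(rbind(pad, steps, pad), fs = sample_rate, cadence = cadence,
                  noise_sd = noise_sd, step_jitter = 0)
  series <- marker_series(list(heel = b$heel, toe = b$toe),
                          sample_rate = sample_rate, slope_angle = slope,
                          direction_sign = 1,
                          participant_id = "synthetic", trial_id = class)
  list(series = series, truth = b$truth[2, , drop = FALSE])
}

default_class_mix <- function(direction, slope) {
  if (slope == 0) {
    c(normal = 0.85, BTS = 0.05, FTS = 0.01, BHS = 0.04, FHS = 0.04,
      FHS_variant = 0.01)
  } else if (direction == "up") {
    c(normal = 0.55, BTS = 0.24, FTS = 0.00, BHS = 0.16, FHS = 0.04,
      FHS_variant = 0.01)
  } else {
    c(normal = 0.55, BTS = 0.03, FTS = 0.05, BHS = 0.05, FHS = 0.25,
      FHS_variant = 0.07)
  }
}

# draw per-step classes for one bout, honouring the co-occurrence structure:
# uphill backward slips co-occur within a step; a forward toe slip always
# follows a forward heel slip and often shares its step with one
draw_bout_steps <- function(n, mix, co_occurrence = TRUE) {
  cls <- sample(names(mix), n, replace = TRUE, prob = mix)
  # forward toe slips never open a bout and always follow a forward heel slip
  for (k in seq_len(n)) {
    if (cls[k] == "FTS") {
      if (k == 1) cls[k] <- "FHS"
      else if (!cls[k - 1] %in% c("FHS", "FHS_variant")) cls[k - 1] <- "FHS"
    }
  }
  rows <- do.call(rbind, lapply(cls, function(cl) {
    archetype_steps(cl, if (cl == "normal") 0 else default_slip_distance(cl))
  }))
  if (co_occurrence) {
    for (k in seq_len(n)) {
      if (rows$toe_class[k] == "BTS" && rows$heel_class[k] == "none" &&
          runif(1) < 0.5) {
        rows$heel_class[k] <- "BHS"
        rows$d_heel[k] <- default_slip_distance("BHS")
      }
      if (rows$heel_class[k] == "BHS" && rows$toe_class[k] == "none" &&
          runif(1) < 0.5) {
        rows$toe_class[k] <- "BTS"
        rows$d_toe[k] <- default_slip_distance("BTS")
      }
      if (rows$toe_class[k] == "FTS" && rows$heel_class[k] == "none" &&
          runif(1) < 0.40) {
        rows$heel_class[k] <- "FHS"
        rows$d_heel[k] <- default_slip_distance("FHS")
      }
    }
  }
  # vertical slip ripples accompany most (not all) toe slips, and a few
  # ordinary steps show abnormal-swing ripples
  rows$ripple <- ifelse(rows$toe_class != "none", runif(n) < 0.7, runif(n) < 0.08)
  # most abrupt heel slips leave residual motion after contact
  rows$osc <- rows$heel_class != "none" & !rows$variant & runif(n) < 0.85
  # sub-slip forward/backward shuffles on steps without a labelled toe slip
  shuffle <- rows$toe_class == "none" & runif(n) < 0.25
  rows$shuffle_d[shuffle] <- runif(sum(shuffle), 0.002, 0.010) *
    sample(c(-1, 1), sum(shuffle), replace = TRUE, prob = c(0.25, 0.75))
  rows
}

#' Generate a synthetic participant
#'
#' Produces a set of continuous walking bouts for one participant, with a
#' participant-specific gait style (cadence, step length, vertical lift)
#' drawn from the seed so that subjects differ for leave-one-subject-out
#' validation. Bouts alternate ascending and descending across a schedule of
#' slopes; ascending bouts are enriched in backward toe/heel slips and
#' descending bouts in forward heel (and the rarer forward toe) slips.
#' Forward toe slips always follow a forward heel slip.
#'
#' @param participant_id Identifier.
#' @param n_steps Total steps to generate (split into bouts).
#' @param class_mix Optional named archetype proportions (summing to 1) used
#'   for every bout; default: slope/direction-dependent mixes.
#' @param slope_schedule Slopes (degrees) cycled over bout pairs.
#' @param gait_style Optional list overriding `cadence`, `step_length`,
#'   `z_amp`, `variability`.
#' @param steps_per_bout Steps per bout (default 40).
#' @param noise_sd Marker noise SD, metres.
#' @param sample_rate Hz.
#' @param seed RNG seed.
#' @return List with `participant_id`, `style`, and `bouts`: each bout has
#'   `series` (a [marker_series()]), `truth` (per-step ground truth), and
#'   `slope`/`direction` metadata.
#' @export
generate_participant <- function(participant_id = "P1", n_steps = 200,
                                 class_mix = NULL,
                                 slope_schedule = c(0, 3, 5, 7, 9, 11, 12),
                                 gait_style = NULL, steps_per_bout = 40,
                                 noise_sd = 5e-4, sample_rate = 150, seed = 1) {
  old <- local_seed(seed); on.exit(restore_seed(old))
  if (!is.null(class_mix)) {
    if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
    if (!all(names(class_mix) %in% SLIP_CLASSES)) {
      stop("class_mix names must be among: ", paste(SLIP_CLASSES, collapse = ", "))
    }
  }
  style <- list(
    cadence = min(112, max(90, rnorm(1, 100, 4))),
    step_length = min(1.1, max(0.7, rnorm(1, 0.9, 0.05))),
    z_amp = min(1.25, max(0.8, rnorm(1, 1, 0.06))),
    variability = 0.04
  )
  if (!is.null(gait_style)) style <- modifyList(style, gait_style)

  n_bouts <- max(1, ceiling(n_steps / steps_per_bout))
  slopes <- rep(slope_schedule, length.out = n_bouts)
  dirs <- rep(c("up", "down"), length.out = n_bouts)
  bouts <- vector("list", n_bouts)
  for (b in seq_len(n_bouts)) {
    n_b <- min(steps_per_bout, n_steps - (b - 1) * steps_per_bout)
    if (n_b <= 0) break
    mix <- if (is.null(class_mix)) default_class_mix(dirs[b], slopes[b]) else class_mix
    steps <- draw_bout_steps(n_b, mix, co_occurrence = is.null(class_mix))
    bout <- synth_bout(steps, fs = sample_rate, cadence = style$cadence,
                       step_length = style$step_length, z_amp = style$z_amp,
                       step_jitter = style$variability, noise_sd = noise_sd,
                       direction_sign = if (b %% 2 == 0) -1 else 1)
    series <- marker_series(
      list(heel = bout$heel, toe = bout$toe), sample_rate = sample_rate,
      slope_angle = slopes[b], direction_sign = if (b %% 2 == 0) -1 else 1,
      participant_id = participant_id, trial_id = sprintf("bout%02d", b)
    )
    bouts[[b]] <- list(series = series, truth = bout$truth,
                       slope = slopes[b], direction = dirs[b])
  }
  list(participant_id = participant_id, style = style,
       bouts = Filter(Negate(is.null), bouts))
}

#' Simulate a cohort of synthetic participants
#'
#' @param n_participants Number of participants (default 9).
#' @param steps_per_participant Steps per participant (default 1000).
#' @param seed Base seed; participant `i` uses `seed * 100 + i`.
#' @param ... Passed to [generate_participant()].
#' @return List of [generate_participant()] results.
#' @export
simulate_cohort <- function(n_participants = 9, steps_per_participant = 1000,
                            seed = 1, ...) {
  lapply(seq_len(n_participants), function(i) {
    generate_participant(participant_id = sprintf("P%d", i),
                         n_steps = steps_per_participant,
                         seed = seed * 100 + i, ...)
  })
}
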