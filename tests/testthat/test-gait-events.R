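make_peak_signal <- function(n, peaks, width = 10) {
  x <- numeric(n)
  for (p in seq_len(nrow(peaks))) {
    idx <- (peaks$frame[p] - width):(peaks$frame[p] + width)
    idx <- idx[idx >= 1 & idx <= n]
    x[idx] <- x[idx] + peaks$height[p] *
      0.5 * (1 + cos(pi * (idx - peaks$frame[p]) / width))
  }
  x
}

test_that("toe-off: peak + 5 rule, 0.13 m/s threshold, 90-frame separation", {
  # single 0.5 m/s peak at frame 100 -> toe-off at 105
  hv <- make_peak_signal(300, data.frame(frame = 100, height = 0.5))
  kin <- make_kin(300, heel_vert_vel = hv)
  expect_equal(as.integer(detect_toe_off(kin)), 105L)
  # a 0.10 m/s peak is below threshold -> no toe-off
  hv <- make_peak_signal(300, data.frame(frame = 100, height = 0.10))
  expect_length(detect_toe_off(make_kin(300, heel_vert_vel = hv)), 0)
  # two 0.5 m/s peaks 50 frames apart -> only the (slightly) larger retained
  hv <- make_peak_signal(400, data.frame(frame = c(100, 150), height = c(0.5, 0.51)))
  to <- detect_toe_off(make_kin(400, heel_vert_vel = hv))
  expect_equal(as.integer(to), 155L)
  # returned toe-offs never violate the separation
  expect_true(all(diff(attr(to, "peaks")) >= 90 | length(to) < 2))
})

test_that("peak detection is equivalent to a brute-force O(n^2) scan", {
  set.seed(42)
  for (rep_i in 1:12) {
    n <- sample(50:1000, 1)
    x <- as.numeric(stats::filter(rnorm(n), rep(1 / 4, 4), sides = 2))
    x[is.na(x)] <- 0
    h <- sample(c(-Inf, 0, 0.3), 1)
    sp <- sample(c(0, 5, 25), 1)
    pr <- sample(c(0, 0.1), 1)
    got <- find_peaks(x, min_height = h, min_separation = sp, min_prominence = pr)
    expect_equal(got$frame, naive_peaks(x, h, sp, pr),
                 info = sprintf("rep %d n=%d h=%g sp=%g pr=%g", rep_i, n, h, sp, pr))
  }
})

test_that("heel contact is recovered near truth on generated steps; flat signals give none", {
  for (cl in c("normal", "BHS", "FHS")) {
    st <- generate_step(cl, slip_distance = if (cl == "normal") 0 else 0.03,
                        noise_sd = 5e-4, seed = 21)
    ft <- featurize_trial(st$series)
    expect_equal(nrow(ft$strides), 1)
    expect_lte(abs(ft$strides$heel_contact - st$truth$hc_truth), 5)
  }
  # standing still: no toe-offs, no heel contacts
  kin <- make_kin(600, heel_vert_vel = 0)
  to <- detect_toe_off(kin)
  expect_length(to, 0)
  expect_length(detect_heel_contact(kin, to), 0)
})

test_that("a low trough in a toe-down swing posture is rejected by the foot-angle gate", {
  n <- 400
  # two toe-offs around a window with two candidate troughs
  hv <- make_peak_signal(n, data.frame(frame = c(80, 300), height = c(0.8, 0.8)))
  tr <- make_peak_signal(n, data.frame(frame = c(150, 220), height = c(0.6, 0.5)))
  hv <- hv - tr
  # heel high through swing, low at both candidate troughs (height gate
  # passes for both)
  hz <- rep(0.1, n)
  hz[140:160] <- 0.01
  hz[210:230] <- 0.01
  # foot angle: deep toe-down at the first trough, landing posture at the second
  ang <- rep(6.84, n)
  ang[130:170] <- -20
  kin <- make_kin(n, heel_vert_vel = hv, heel_vert_pos = hz, foot_angle = ang)
  to <- detect_toe_off(kin)
  hc <- detect_heel_contact(kin, to)
  expect_equal(length(hc), 1)
  # the swing-apex trough (150) is rejected; contact comes from the 220 trough
  expect_gte(hc[1], 220)
  expect_lt(hc[1], 300)
})

test_that("stride assembly follows the midpoint rule and drops incomplete strides and turns", {
  n <- 1200
  to <- c(100, 280, 460, 640)
  hc <- c(160, 340, 520)
  kin <- make_kin(n, heel_ap_vel = 1)
  events <- list(toe_offs = to, heel_contacts = hc)
  strides <- assemble_strides(kin, events)
  # 4 toe-offs with 3 contacts -> exactly 2 complete strides
  expect_equal(nrow(strides), 2)
  expect_equal(strides$start, c(round((160 + 280) / 2), round((340 + 460) / 2)))
  expect_equal(strides$end, c(round((340 + 460) / 2), round((520 + 640) / 2)))
  expect_true(all(strides$start < strides$toe_off &
                    strides$toe_off < strides$heel_contact &
                    strides$heel_contact < strides$end))
  # a missing heel contact removes exactly the strides that need it
  events_na <- list(toe_offs = to, heel_contacts = c(160, NA, 520))
  expect_equal(nrow(assemble_strides(kin, events_na)), 0)
  # sustained AP reversal (a turn) removes overlapping strides
  v <- rep(1, n); v[300:390] <- -1  # 0.6 s reversal
  kin_turn <- make_kin(n, heel_ap_vel = v)
  strides_turn <- assemble_strides(kin_turn, events)
  expect_equal(nrow(strides_turn), 1)
  expect_gte(strides_turn$start, 390)
  # a brief negative excursion (a slip, not a turn) removes nothing
  v2 <- rep(1, n); v2[300:340] <- -1  # 0.27 s < 0.5 s gate
  expect_equal(nrow(assemble_strides(make_kin(n, heel_ap_vel = v2), events)), 2)
})

test_that("Bland-Altman timing: identity, constant offset, dispersion", {
  fs <- 150
  ref <- c(100, 250, 400, 550)
  # identical events
  ba <- bland_altman_timing(ref, ref, fs)
  expect_equal(ba$mean_error_ms, 0)
  expect_equal(ba$loa_low_ms, 0)
  expect_equal(ba$loa_high_ms, 0)
  # constant +3 frames = +20 ms, LoA collapse onto the mean
  ba3 <- bland_altman_timing(ref + 3, ref, fs)
  expect_equal(ba3$mean_error_ms, 20)
  expect_equal(ba3$loa_low_ms, 20)
  expect_equal(ba3$loa_high_ms, 20)
  # differences of -1, 0, +1 frames
  det <- ref[1:3] + c(-1, 0, 1)
  bad <- bland_altman_timing(det, ref[1:3], fs)
  d_ms <- c(-1, 0, 1) / fs * 1000
  expect_equal(bad$mean_error_ms, 0)
  expect_equal(bad$loa_high_ms, 1.96 * sd(d_ms))
  # unmatched events are excluded and reported
  ba_un <- bland_altman_timing(c(ref, 1000), ref, fs)
  expect_equal(ba_un$n_matched, 4)
  expect_equal(ba_un$n_unmatched_detected, 1)
})

test_that("noiseless generator bouts: toe-off equals truth peak + 5 exactly, separations hold", {
  p <- generate_participant("P1", n_steps = 25, noise_sd = 0, seed = 13)
  bt <- p$bouts[[1]]
  ft <- featurize_trial(bt$series)
  to <- ft$events$toe_offs
  expect_true(all(diff(to) >= 90))
  # every detected toe-off coincides with a truth toe-off (peak + 5)
  expect_true(all(to %in% bt$truth$to_truth))
  expect_true(all(to %in% (bt$truth$peak_truth + 5)))
  # heel contacts exact on noiseless signals
  hc <- ft$strides$heel_contact
  expect_true(all(apply(abs(outer(hc, bt$truth$hc_truth, "-")), 1, min) <= 5))
})
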