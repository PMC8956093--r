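test_that("curvature: zero for linear, v'' at a quadratic vertex, boundary errors", {
  t <- 1:50
  expect_equal(curvature(0.3 * t + 2, 10), 0, tolerance = 1e-12)
  # quadratic with vertex at t0: v'(t0) = 0 so kappa = v'' (per-frame units)
  a <- 0.02; t0 <- 25
  v <- a * (t - t0)^2
  expect_equal(curvature(v, t0), 2 * a, tolerance = 1e-12)
  expect_error(curvature(v, 1), "interior")
  expect_error(curvature(v, 50), "interior")
})

test_that("curvature matches the analytic formula on a quadratic (exact central differences)", {
  t <- 1:80
  v <- 0.005 * t^2 - 0.3 * t + 1
  for (ti in c(2, 17, 40, 79)) {
    d1 <- 0.01 * ti - 0.3          # dv/dt, per-frame
    d2 <- 0.01                     # d2v/dt2, per-frame
    expect_equal(curvature(v, ti), d2 / (1 + d1^2)^1.5, tolerance = 1e-9)
  }
})

test_that("anchors: heel-off threshold rule, argmax with earliest tie-break, absence", {
  fs <- 150
  n <- 300
  stride <- data.frame(start = 50, toe_off = 150, heel_contact = 210, end = 280)
  # stationary then smoothly accelerating heel from frame 120
  t <- 0:(n - 1)
  ha <- pmax(0, (t - 120)) / fs * 3   # accel 3 m/s^2 from frame 120
  kin <- make_kin(n, heel_ap_vel = ha)
  anch <- find_anchors(kin, stride)
  # first frame with acc >= 0.5 while vel < 0.1: right at the ramp start
  expect_true(anch$t_heel_off %in% 119:123)
  expect_lt(kin$heel_vel[anch$t_heel_off, "ap"], 0.1)
  # monotone velocity -> T_max_velocity at the stride end
  expect_equal(anch$t_max_velocity, 280)
  # velocity never below 0.1 -> no heel-off anchor
  kin2 <- make_kin(n, heel_ap_vel = 1 + ha)
  expect_true(is.na(find_anchors(kin2, stride)$t_heel_off))
  # constant velocity: argmax ties broken by the earliest frame
  kin3 <- make_kin(n, heel_ap_vel = 1)
  expect_equal(find_anchors(kin3, stride)$t_max_velocity, 50)
})

test_that("peak inventory: analytic half-sine area, monotone signals, 7 ms merging", {
  fs <- 150
  # positive half-sine lobe: amplitude A, duration D -> area 2AD/pi
  A <- 0.8; D <- 0.2
  n <- 120; s0 <- 40; len <- round(D * fs)
  x <- numeric(n)
  x[s0:(s0 + len)] <- A * sin(pi * (0:len) / len)
  inv <- peak_inventory(x, fs, polarity = "positive")
  expect_equal(nrow(inv), 1)
  expect_equal(inv$area, 2 * A * D / pi, tolerance = 0.02)
  expect_equal(inv$width_s, D, tolerance = 0.05)
  # monotone signal: no peaks
  expect_equal(nrow(peak_inventory(seq(0, 1, length.out = 100), fs,
                                   polarity = "positive")), 0)
  # two peaks 5 ms apart at 1 kHz with a 7 ms separation: larger retained
  y <- numeric(100)
  y[42:53] <- c(0.2, 0.4, 0.5, 0.4, 0.3, 0.3, 0.4, 0.6, 0.5, 0.3, 0.1, 0.05)
  inv2 <- peak_inventory(y, 1000, polarity = "positive", min_separation_ms = 7)
  expect_equal(nrow(inv2), 1)
  expect_equal(inv2$height, 0.6)
  inv3 <- peak_inventory(y, 1000, polarity = "positive", min_separation_ms = 2)
  expect_equal(nrow(inv3), 2)
})

test_that("feature vectors on archetype steps carry the designed signatures", {
  # normal step: no post-contact AP peaks, full stop reached
  st <- generate_step("normal", noise_sd = 5e-4, seed = 31)
  f <- featurize_trial(st$series)$features
  expect_equal(f$f11, 0)
  expect_equal(f$f17, 1)
  # forward heel slip: post-contact positive lobe area equals the slip distance
  st <- generate_step("FHS", slip_distance = 0.05, noise_sd = 0, seed = 32)
  f <- featurize_trial(st$series)$features
  expect_equal(f$f13, 0.05, tolerance = 0.02)
  expect_gte(f$f11, 1)
  # backward toe slip: pre-toe-off negative toe AP lobe
  st <- generate_step("BTS", slip_distance = 0.03, noise_sd = 0, seed = 33)
  f <- featurize_trial(st$series)$features
  expect_gte(f$f26, 1)
  expect_gt(f$f29, 0)
  expect_equal(f$f29, 0.03, tolerance = 0.1)
})

test_that("feature values are invariant to uniform time translation of the stride", {
  # a jitter-free noiseless bout repeats the same cycle at shifted times
  p <- generate_participant("P1", n_steps = 6, noise_sd = 0, seed = 3,
                            gait_style = list(variability = 0),
                            class_mix = c(normal = 1, BTS = 0, FTS = 0,
                                          BHS = 0, FHS = 0, FHS_variant = 0))
  ft <- featurize_trial(p$bouts[[1]]$series)
  f <- ft$features[, paste0("f", 1:36)]
  expect_gte(nrow(f), 3)
  mid <- 2:(nrow(f) - 1)  # interior strides (33/34 need a following stride)
  for (i in mid[-1]) {
    expect_equal(as.numeric(f[i, ]), as.numeric(f[mid[1], ]), tolerance = 1e-6)
  }
})

test_that("AP sign flip maps backward-slip features onto their forward mirrors", {
  st <- generate_step("BTS", slip_distance = 0.04, noise_sd = 0, seed = 8)
  ft <- featurize_trial(st$series)
  kin <- ft$kin
  # negate the AP axis of every AP-derived signal
  kin_m <- kin
  kin_m$heel_pos[, "ap"] <- -kin$heel_pos[, "ap"]
  kin_m$toe_pos[, "ap"] <- -kin$toe_pos[, "ap"]
  kin_m$heel_vel[, "ap"] <- -kin$heel_vel[, "ap"]
  kin_m$toe_vel[, "ap"] <- -kin$toe_vel[, "ap"]
  kin_m$heel_acc_ap <- -kin$heel_acc_ap
  f0 <- compute_feature_vector(kin, ft$strides[1, ])$values
  f1 <- compute_feature_vector(kin_m, ft$strides[1, ])$values
  # negative toe AP peaks (26) become positive ones (21), heights mirror (28 vs 23)
  expect_equal(unname(f1["f21"]), unname(f0["f26"]))
  expect_equal(unname(f1["f23"]), unname(-f0["f28"]), tolerance = 1e-9)
  expect_equal(unname(f1["f26"]), unname(f0["f21"]))
})

test_that("histogram overlap: identical, disjoint, and Gaussian cases", {
  set.seed(7)
  # identical class distributions -> overlap 1, discarded
  x <- rnorm(400)
  feats <- data.frame(f_same = c(x, x), f_apart = c(rnorm(400, 0), rnorm(400, 50)))
  labels <- rep(c("A", "B"), each = 400)
  sel <- histogram_overlap_selection(feats, labels)
  s <- sel$summary
  expect_equal(s$max_overlap[s$feature == "f_same"], 1, tolerance = 0.08)
  expect_false(s$kept[s$feature == "f_same"])
  # disjoint supports -> overlap 0, kept
  expect_equal(s$max_overlap[s$feature == "f_apart"], 0, tolerance = 1e-9)
  expect_true(s$kept[s$feature == "f_apart"])
  # two unit Gaussians two SD apart: overlap = 2 * pnorm(-1) (quadrature value)
  g <- data.frame(f_g = c(rnorm(4000, 0), rnorm(4000, 2)))
  lg <- rep(c("A", "B"), each = 4000)
  sg <- histogram_overlap_selection(g, lg)
  expect_equal(sg$summary$max_overlap, 2 * pnorm(-1), tolerance = 0.05)
  # degenerate inputs
  expect_error(histogram_overlap_selection(feats, rep("A", 800)), "2 classes")
  expect_error(histogram_overlap_selection(feats, labels, bins = 1), "bins")
})

test_that("tiny classes skip pairs but are reported", {
  feats <- data.frame(f1 = c(rnorm(50), 5))
  labels <- c(rep("A", 50), "B")
  sel <- histogram_overlap_selection(feats, labels)
  expect_true(is.na(sel$summary$max_overlap))
  expect_equal(nrow(sel$skipped_pairs), 1)
  expect_true(sel$summary$kept)  # nothing to condemn it on
})

test_that("long-format export carries one row per stride and feature with validity", {
  st <- generate_step("normal", noise_sd = 0, seed = 5)
  feats <- featurize_trial(st$series)$features
  long <- feature_table_long(feats)
  expect_equal(nrow(long), nrow(feats) * 36)
  expect_true(all(long$feature_id %in% 1:36))
  expect_true(is.logical(long$valid))
})

test_that("histogram-overlap selection retains both classifiers' feature subsets on well-separated data", {
  # noiseless cohort with strong, co-occurring slip signatures: every
  # catalogue-selected feature must survive the 75% overlap cut
  cohort <- simulate_cohort(3, 300, seed = 5, noise_sd = 0)
  ds <- build_dataset(cohort)
  for (taxo in c("toe", "heel")) {
    sel <- histogram_overlap_selection(ds[, paste0("f", 1:36)],
                                       ds[[paste0(taxo, "_class")]],
                                       bins = 50, overlap_cutoff = 0.75)
    missing <- setdiff(paste0("f", selected_features(taxo)), sel$kept)
    expect_length(missing, 0)
  }
})
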