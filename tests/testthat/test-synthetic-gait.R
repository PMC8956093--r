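test_that("class signatures hold on every noiseless archetype step", {
  fs <- 150
  for (seed in 1:5) {
    for (cl in c("BTS", "FTS", "BHS", "FHS", "FHS_variant")) {
      st <- generate_step(cl, noise_sd = 0, seed = seed)
      series <- st$series
      tr <- st$truth
      ha <- differentiate_signal(series$markers$heel[, "ap"], fs)
      ta <- differentiate_signal(series$markers$toe[, "ap"], fs)
      pre <- (tr$to_truth - 45):(tr$to_truth - 1)
      post <- (tr$hc_truth + 1):(tr$hc_truth + 40)
      msg <- paste(cl, seed)
      if (cl == "BTS") {
        expect_lt(min(ta[pre]), -0.05)  # backward toe motion before toe-off
      } else if (cl == "FTS") {
        pk <- find_peaks(ha[pre], min_height = 0.05, min_prominence = 0.02)
        expect_gte(nrow(pk), 1)         # extra forward maximum before toe-off
      } else if (cl == "BHS") {
        expect_lt(min(ha[post]), -0.05) # backward heel motion after contact
      } else if (cl == "FHS") {
        pk <- find_peaks(ha[post], min_height = 0.05, min_prominence = 0.02)
        expect_gte(nrow(pk), 1)         # forward maximum after contact
      } else {
        expect_gt(ha[tr$hc_truth], 0.15)  # elevated AP velocity at contact
        pk <- find_peaks(ha[post], min_height = 0.02, min_prominence = 0.02)
        expect_equal(nrow(pk), 0)         # but no post-contact maximum
        expect_lt(ha[tr$hc_truth + 40], ha[tr$hc_truth])  # gradual decay
      }
    }
  }
})

test_that("slip-distance accounting: archetype rules and realistic range", {
  expect_error(generate_step("normal", slip_distance = 0.02), "slip_distance 0")
  expect_error(generate_step("BTS", slip_distance = 0), "> 0")
  expect_error(generate_step("BTS", slip_distance = -1), ">= 0")
  # cohort slip distances span below 1.5 cm to above 6 cm
  p <- generate_participant("P1", n_steps = 400, seed = 27)
  d <- unlist(lapply(p$bouts, function(b) b$truth$slip_distance[b$truth$slip]))
  expect_lt(min(d), 0.015)
  expect_gt(max(d), 0.06)
  # slip_distance = 0 iff the step is not a slip
  truth <- do.call(rbind, lapply(p$bouts, `[[`, "truth"))
  expect_identical(truth$slip_distance > 0, truth$slip)
})

test_that("participants are deterministic given a seed and differ across seeds", {
  p1 <- generate_participant("P1", n_steps = 40, seed = 101)
  p2 <- generate_participant("P1", n_steps = 40, seed = 101)
  expect_identical(p1$bouts[[1]]$series$markers, p2$bouts[[1]]$series$markers)
  expect_identical(p1$bouts[[1]]$truth, p2$bouts[[1]]$truth)
  p3 <- generate_participant("P1", n_steps = 40, seed = 102)
  expect_false(identical(p1$bouts[[1]]$series$markers,
                         p3$bouts[[1]]$series$markers))
  # styles vary between participants
  expect_false(isTRUE(all.equal(p1$style$cadence, p3$style$cadence)))
})

test_that("class mix is honoured: all-normal mix yields zero slips; slip fraction tracks the mix", {
  mix0 <- c(normal = 1, BTS = 0, FTS = 0, BHS = 0, FHS = 0, FHS_variant = 0)
  p <- generate_participant("P1", n_steps = 60, class_mix = mix0, seed = 3)
  truth <- do.call(rbind, lapply(p$bouts, `[[`, "truth"))
  expect_equal(sum(truth$slip), 0)
  mix4 <- c(normal = 0.6, BTS = 0.1, FTS = 0, BHS = 0.1, FHS = 0.15,
            FHS_variant = 0.05)
  p4 <- generate_participant("P1", n_steps = 500, class_mix = mix4, seed = 4)
  truth4 <- do.call(rbind, lapply(p4$bouts, `[[`, "truth"))
  expect_equal(mean(truth4$slip), 0.4, tolerance = 0.08)
  expect_error(generate_participant("P", class_mix = c(normal = 0.5)), "sum to 1")
})

test_that("forward toe slips always follow a forward heel slip within the bout", {
  found <- 0
  for (seed in 1:6) {
    p <- generate_participant("P1", n_steps = 300, seed = seed * 7)
    for (b in p$bouts) {
      tr <- b$truth
      fts <- which(tr$toe_class == "FTS")
      found <- found + length(fts)
      for (k in fts) {
        expect_gt(k, 1)
        expect_equal(tr$heel_class[k - 1], "FHS")
      }
    }
  }
  expect_gt(found, 0)  # the scenario actually occurs
})

test_that("generated bouts segment cleanly: stride ordering and event recovery under noise", {
  p <- generate_participant("P1", n_steps = 40, seed = 55)
  bt <- p$bouts[[1]]
  ft <- featurize_trial(bt$series)
  s <- ft$strides
  expect_true(all(s$start < s$toe_off & s$toe_off < s$heel_contact &
                    s$heel_contact < s$end))
  # almost every interior truth step is recovered
  expect_gte(nrow(s), nrow(bt$truth) - 3)
  m <- match_truth(s, bt$truth)
  expect_equal(attr(m, "n_unmatched"), 0)
  # toe-offs within a frame or two of truth even with noise
  to_err <- abs(m$toe_off - bt$truth$to_truth[match(m$toe_off - 0, bt$truth$to_truth)])
  d <- apply(abs(outer(s$toe_off, bt$truth$to_truth, "-")), 1, min)
  expect_lte(max(d), 3)
})
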