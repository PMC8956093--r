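test_that("z-score normalization: textbook value, degenerate column, self-application", {
  train <- cbind(a = c(3, 5, 7), b = c(1, 1, 1))
  # hand z-score: column mean 5, sd 2 -> value 7 maps to 1
  nrm <- normalize_fit_apply(train, cbind(a = 7, b = 1))
  expect_equal(unname(nrm$apply_to[1, "a"]), 1)
  # constant column maps to zero everywhere
  expect_equal(unname(nrm$train[, "b"]), c(0, 0, 0))
  # applying to the training table gives mean 0, sd 1
  expect_equal(unname(colMeans(nrm$train)), c(0, 0))
  expect_equal(unname(sd(nrm$train[, "a"])), 1)
  expect_error(normalize_fit_apply(train, cbind(a = 1)), "absent")
  expect_error(normalize_fit_apply(train[0, , drop = FALSE]), "empty")
})

test_that("one-vs-rest linear SVM separates separable blobs and is scale-stable", {
  set.seed(2)
  x <- rbind(cbind(rnorm(50, 0), rnorm(50, 0)),
             cbind(rnorm(50, 6), rnorm(50, 6)),
             cbind(rnorm(50, 6), rnorm(50, -6)))
  y <- rep(c("NTS", "BTS", "FTS"), each = 50)
  m <- train_ovr_linear_svm(x, y, C = 1, no_slip = "NTS")
  expect_equal(mean(predict_ovr(m, x) == y), 1)  # 100% training accuracy
  # duplicated training set -> same decision boundary
  m2 <- train_ovr_linear_svm(rbind(x, x), c(y, y), C = 1, no_slip = "NTS")
  for (cl in m$classes) {
    w1 <- m$fits[[cl]]$w / sqrt(sum(m$fits[[cl]]$w^2))
    w2 <- m2$fits[[cl]]$w / sqrt(sum(m2$fits[[cl]]$w^2))
    expect_equal(w1, w2, tolerance = 1e-4)
  }
  expect_error(train_ovr_linear_svm(x, rep("NTS", 150)), "single-class")
})

test_that("under-sampling balances the no-slip class per the stated rule, deterministically", {
  labels <- c(rep("NHS", 1000), rep("BHS", 100), rep("FHS", 150))
  idx <- undersample(labels, "NHS", seed = 4, repeat_index = 1)
  tab <- table(labels[idx])
  expect_equal(unname(tab["NHS"]), 250)  # equals total slip count
  expect_equal(unname(tab["BHS"]), 100)  # slip classes kept in full
  expect_equal(unname(tab["FHS"]), 150)
  # same (seed, repeat) -> identical subset; different repeat -> different subset
  expect_identical(idx, undersample(labels, "NHS", seed = 4, repeat_index = 1))
  expect_false(identical(idx, undersample(labels, "NHS", seed = 4, repeat_index = 2)))
  # already balanced or minority no-slip: unchanged
  bal <- c(rep("NHS", 100), rep("BHS", 100))
  expect_identical(undersample(bal, "NHS", 1, 1), seq_along(bal))
})

test_that("binary slip decision equals the four-indicator disjunction on every combination", {
  combos <- expand.grid(toe = c("NTS", "BTS", "FTS"),
                        heel = c("NHS", "BHS", "FHS"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    ind <- c(bts = combos$toe[i] == "BTS", fts = combos$toe[i] == "FTS",
             bhs = combos$heel[i] == "BHS", fhs = combos$heel[i] == "FHS")
    expect_identical(slip_flag(combos$toe[i], combos$heel[i]),
                     any(ind),
                     info = paste(combos$toe[i], combos$heel[i]))
  }
  # a step with both a toe and a heel slip is a single slip, flagged once
  expect_true(slip_flag("BTS", "BHS"))
  expect_false(slip_flag("NTS", "NHS"))
})

test_that("model training is reproducible and round-trips through serialization", {
  dat <- make_blob_data(seed = 5)
  m1 <- train_slip_model(dat, "toe", seed = 11)
  m2 <- train_slip_model(dat, "toe", seed = 11)
  expect_identical(m1$model$fits, m2$model$fits)  # bit-for-bit
  expect_identical(m1$C, m2$C)
  # prediction consistency after JSON round trip
  path <- tempfile(fileext = ".json")
  models <- list(toe = m1, heel = m1)  # reuse toe model in both slots
  models$heel$taxonomy <- "heel"
  save_slip_models(models, path)
  back <- load_slip_models(path)
  p1 <- predict_slip_model(m1, dat)
  p2 <- predict_slip_model(back$toe, dat)
  expect_identical(as.character(p1), as.character(p2))
})

test_that("prediction ties resolve to the no-slip class", {
  m <- list(classes = c("BTS", "FTS", "NTS"),
            fits = list(BTS = list(w = c(0, 0), b = 0, platt = c(0, 1)),
                        FTS = list(w = c(0, 0), b = 0, platt = c(0, 1)),
                        NTS = list(w = c(0, 0), b = 0, platt = c(0, 1))),
            no_slip = "NTS", score = "platt", n_features = 2,
            feature_names = c("f1", "f2"))
  class(m) <- "ovr_svm"
  pred <- predict_ovr(m, matrix(0, 3, 2))
  expect_true(all(pred == "NTS"))
})
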