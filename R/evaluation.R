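#' Precision, recall and F1 from confusion counts
#'
#' Precision = tp / (tp + fp); recall = tp / (tp + fn); F1 is the harmonic
#' mean of the two. A metric whose denominator is zero is *absent* (`NA`),
#' never reported as zero.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return List with `precision`, `recall`, `f1`.
#' @examples
#' classification_metrics(9, 1, 3)  # precision 0.9, recall 0.75, F1 0.818
#' @export
classification_metrics <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- f1_score(precision, recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Metric values in \[0, 1\] (NA allowed).
#' @return `2 * p * r / (p + r)`, or `NA` when either input is absent or the
#'   sum is zero.
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

confusion_counts <- function(pred, truth, classes) {
  do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(truth == cl & pred != cl)
    m <- classification_metrics(tp, fp, fn)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  }))
}

macro_f1 <- function(pred, truth, classes) {
  cc <- confusion_counts(pred, truth, classes)
  mean(cc$f1, na.rm = TRUE)
}

#' Leave-one-subject-out cross-validation of the slip classifiers
#'
#' One fold per participant: the participant's steps are the test set and
#' are never used for under-sampling, normalization, feature selection or
#' cost tuning. Within each fold the training pool is under-sampled
#' `repeats` times; each repeat trains both taxonomy classifiers (cost tuned
#' once per fold, on the first repeat's 80:20 validation split) and
#' evaluates them on the held-out participant. The binary slip decision is
#' the inclusive-or of the two classifiers' slip labels. Results are
#' averaged over repeats within fold, then over folds.
#'
#' @param data data.frame with `participant`, `toe_class`, `heel_class` and
#'   feature columns `f1`..`f36`.
#' @param config A [pipeline_config()] or list of overrides.
#' @param seed Base seed.
#' @param repeats Number of under-sampling repeats (default from config).
#' @param progress Print per-fold progress to stderr.
#' @return Object of class `"slip_eval"`: `folds` (per taxonomy x fold x
#'   repeat x class counts and metrics), `summary` (per-class averages and
#'   the class-average row, as percentages), `overall` and
#'   `overall_summary` (binary slip detection), `skipped_folds`.
#' @export
losocv <- function(data, config = NULL, seed = 1, repeats = NULL,
                   progress = FALSE) {
  cfg <- as_config(config)
  if (is.null(repeats)) repeats <- cfg$classifier$repeats
  participants <- sort(unique(data$participant))
  if (length(participants) < 3) stop("LOSOCV needs at least 3 participants")
  fold_rows <- list(); overall_rows <- list(); skipped <- character(0)

  for (fi in seq_along(participants)) {
    p <- participants[fi]
    test <- data[data$participant == p, , drop = FALSE]
    pool <- data[data$participant != p, , drop = FALSE]
    if (nrow(test) == 0) { skipped <- c(skipped, as.character(p)); next }
    if (progress) message(sprintf("fold %d/%d (participant %s)", fi,
                                  length(participants), p))
    tuned_C <- list(toe = NULL, heel = NULL)
    for (rep_i in seq_len(repeats)) {
      preds <- list()
      for (taxo in c("toe", "heel")) {
        sm <- train_slip_model(pool, taxo, cfg,
                               seed = seed + 1000 * fi, repeat_index = rep_i,
                               C = tuned_C[[taxo]])
        tuned_C[[taxo]] <- sm$C
        tx <- TAXONOMIES[[taxo]]
        pred <- predict_slip_model(sm, test)
        preds[[taxo]] <- pred
        cc <- confusion_counts(pred, as.character(test[[tx$column]]), tx$classes)
        cc$taxonomy <- taxo; cc$participant <- p; cc$rep <- rep_i; cc$C <- sm$C
        fold_rows[[length(fold_rows) + 1]] <- cc
      }
      slip_pred <- slip_flag(preds$toe, preds$heel)
      slip_truth <- slip_flag(as.character(test$toe_class),
                              as.character(test$heel_class))
      tp <- sum(slip_pred & slip_truth)
      fp <- sum(slip_pred & !slip_truth)
      fn <- sum(!slip_pred & slip_truth)
      m <- classification_metrics(tp, fp, fn)
      overall_rows[[length(overall_rows) + 1]] <- data.frame(
        participant = p, rep = rep_i, tp = tp, fp = fp, fn = fn,
        precision = m$precision, recall = m$recall, f1 = m$f1
      )
    }
  }

  folds <- do.call(rbind, fold_rows)
  overall <- do.call(rbind, overall_rows)
  out <- list(
    folds = folds,
    summary = summarize_folds(folds),
    overall = overall,
    overall_summary = summarize_overall(overall),
    skipped_folds = skipped,
    repeats = repeats, seed = seed,
    participants = participants
  )
  class(out) <- "slip_eval"
  out
}

# mean over repeats within fold, then over folds; percentages
summarize_folds <- function(folds) {
  out <- list()
  for (taxo in unique(folds$taxonomy)) {
    ft <- folds[folds$taxonomy == taxo, ]
    per_class <- do.call(rbind, lapply(unique(ft$class), function(cl) {
      fc <- ft[ft$class == cl, ]
      by_fold <- aggregate(fc[, c("precision", "recall", "f1")],
                           by = list(participant = fc$participant),
                           FUN = mean, na.rm = TRUE)
      data.frame(taxonomy = taxo, class = cl,
                 precision = 100 * mean(by_fold$precision, na.rm = TRUE),
                 recall = 100 * mean(by_fold$recall, na.rm = TRUE),
                 f1 = 100 * mean(by_fold$f1, na.rm = TRUE))
    }))
    avg_p <- mean(per_class$precision)
    avg_r <- mean(per_class$recall)
    avg <- data.frame(taxonomy = taxo, class = "Average",
                      precision = avg_p, recall = avg_r,
                      f1 = mean(per_class$f1))
    # alternative average: harmonic mean of the averaged precision/recall
    avg$f1_of_averages <- 100 * f1_score(avg_p / 100, avg_r / 100)
    per_class$f1_of_averages <- NA_real_
    out[[taxo]] <- rbind(per_class, avg)
  }
  do.call(rbind, out)
}

summarize_overall <- function(overall) {
  by_fold <- aggregate(overall[, c("precision", "recall", "f1")],
                       by = list(participant = overall$participant),
                       FUN = mean, na.rm = TRUE)
  list(precision = 100 * mean(by_fold$precision, na.rm = TRUE),
       recall = 100 * mean(by_fold$recall, na.rm = TRUE),
       f1 = 100 * mean(by_fold$f1, na.rm = TRUE))
}

#' @export
print.slip_eval <- function(x, ...) {
  cat("<slip_eval> leave-one-subject-out cross-validation\n")
  cat(sprintf("  %d participants, %d under-sampling repeats\n",
              length(x$participants), x$repeats))
  for (taxo in unique(x$summary$taxonomy)) {
    cat(sprintf("\n  %s-slip classifier (percent):\n", taxo))
    s <- x$summary[x$summary$taxonomy == taxo,
                   c("class", "precision", "recall", "f1")]
    s[, -1] <- round(s[, -1], 1)
    print(s, row.names = FALSE)
  }
  os <- x$overall_summary
  cat(sprintf("\n  overall slip detection: precision %.1f%%, recall %.1f%%, F1 %.1f%%\n",
              os$precision, os$recall, os$f1))
  invisible(x)
}

#' Event-timing sensitivity analysis
#'
#' Shifts the toe-off and heel-contact timings of a sample of steps
#' independently by a grid of frame offsets, re-extracts the features with
#' the perturbed timing, feeds them to trained classifiers, and reports the
#' macro-F1 of each classifier per offset together with its change relative
#' to offset zero. A step is excluded for an offset when the perturbed event
#' leaves its stride bounds (counted per offset).
#'
#' @param models List with `toe` and `heel` `"slip_model"`s.
#' @param trials List of trials, each a list with `kin` (a
#'   [compute_foot_signals()] result) and `strides` (stride data.frame with
#'   `toe_class` and `heel_class` truth columns).
#' @param offsets Integer frame offsets (default -15..15).
#' @param events Which events to perturb.
#' @param config A [pipeline_config()] or list of overrides.
#' @return data.frame with `event`, `offset`, `toe_f1`, `heel_f1`,
#'   `d_toe_f1`, `d_heel_f1`, `n_steps`, `n_excluded`.
#' @export
sensitivity_analysis <- function(models, trials, offsets = -15:15,
                                 events = c("toe_off", "heel_contact"),
                                 config = NULL) {
  cfg <- as_config(config)
  events <- match.arg(events, several.ok = TRUE)
  if (!0 %in% offsets) offsets <- sort(c(0, offsets))
  rows <- list()
  for (ev in events) {
    for (off in offsets) {
      preds <- list(); truth_toe <- character(0); truth_heel <- character(0)
      n_excl <- 0
      feats_all <- list()
      for (tr in trials) {
        st <- tr$strides
        if (ev == "toe_off") st$toe_off <- st$toe_off + off
        else st$heel_contact <- st$heel_contact + off
        keep <- st$start < st$toe_off & st$toe_off < st$heel_contact &
          st$heel_contact < st$end
        n_excl <- n_excl + sum(!keep)
        st <- st[keep, , drop = FALSE]
        if (nrow(st) == 0) next
        f <- compute_features(tr$kin, st, cfg)
        feats_all[[length(feats_all) + 1]] <- f
        truth_toe <- c(truth_toe, as.character(st$toe_class))
        truth_heel <- c(truth_heel, as.character(st$heel_class))
      }
      feats <- do.call(rbind, lapply(feats_all, function(f) f[, paste0("f", 1:36)]))
      toe_pred <- predict_slip_model(models$toe, feats)
      heel_pred <- predict_slip_model(models$heel, feats)
      rows[[length(rows) + 1]] <- data.frame(
        event = ev, offset = off,
        toe_f1 = macro_f1(toe_pred, truth_toe, TAXONOMIES$toe$classes),
        heel_f1 = macro_f1(heel_pred, truth_heel, TAXONOMIES$heel$classes),
        n_steps = length(toe_pred), n_excluded = n_excl
      )
    }
  }
  out <- do.call(rbind, rows)
  for (ev in unique(out$event)) {
    base <- out[out$event == ev & out$offset == 0, ]
    sel <- out$event == ev
    out$d_toe_f1[sel] <- out$toe_f1[sel] - base$toe_f1
    out$d_heel_f1[sel] <- out$heel_f1[sel] - base$heel_f1
  }
  out
}
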