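#' Segment and featurize one trial
#'
#' Runs the standard chain on a marker series: participant-centric frame,
#' foot signal derivation, toe-off and heel-contact detection, stride
#' assembly, feature extraction.
#'
#' @param series A [marker_series()].
#' @param config A [pipeline_config()] or list of overrides.
#' @return List with `kin`, `events` (`toe_offs`, `heel_contacts`),
#'   `strides`, `features`.
#' @export
featurize_trial <- function(series, config = NULL) {
  cfg <- as_config(config)
  series <- to_participant_frame(series)
  kin <- compute_foot_signals(series, cfg)
  to <- detect_toe_off(kin, cfg)
  hc <- detect_heel_contact(kin, to, cfg)
  events <- list(toe_offs = to, heel_contacts = hc)
  strides <- assemble_strides(kin, events, cfg)
  features <- compute_features(kin, strides, cfg)
  list(kin = kin, events = events, strides = strides, features = features)
}

#' Match detected strides to ground-truth steps
#'
#' Pairs each stride with the ground-truth step whose toe-off is nearest
#' (within a tolerance), one-to-one.
#'
#' @param strides Stride (or feature) data.frame with a `toe_off` column.
#' @param truth Ground-truth data.frame with `to_truth` and label columns.
#' @param tolerance_frames Maximum |detected - truth| toe-off distance.
#' @return `strides` with the truth columns appended (labels, slip distance
#'   and the true event frames `to_truth`/`hc_truth`); unmatched strides are
#'   dropped and counted in attribute `"n_unmatched"`.
#' @export
match_truth <- function(strides, truth, tolerance_frames = 15) {
  cols <- c("toe_class", "heel_class", "slip", "slip_distance",
            "to_truth", "hc_truth")
  if (nrow(strides) == 0) {
    out <- cbind(strides, truth[0, cols, drop = FALSE])
    attr(out, "n_unmatched") <- 0
    return(out)
  }
  idx <- rep(NA_integer_, nrow(strides))
  used <- logical(nrow(truth))
  for (i in seq_len(nrow(strides))) {
    d <- abs(truth$to_truth - strides$toe_off[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tolerance_frames) {
      idx[i] <- j
      used[j] <- TRUE
    }
  }
  keep <- !is.na(idx)
  out <- cbind(strides[keep, , drop = FALSE],
               truth[idx[keep], cols, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- sum(!keep)
  out
}

#' Build a labelled step-feature dataset from a synthetic cohort
#'
#' Featurizes every bout of every participant and joins the ground-truth
#' labels by toe-off proximity.
#'
#' @param cohort Result of [simulate_cohort()] (or a list of
#'   [generate_participant()] results).
#' @param config A [pipeline_config()] or list of overrides.
#' @param keep_trials Keep the per-bout `kin`/`strides` objects (needed for
#'   sensitivity and timing analyses) in the `"trials"` attribute.
#' @return data.frame with `participant`, `bout`, labels and `f1`..`f36`;
#'   optionally the per-bout `kin`/`strides` in the `"trials"` attribute.
#' @export
build_dataset <- function(cohort, config = NULL, keep_trials = FALSE) {
  cfg <- as_config(config)
  rows <- list(); trials <- list()
  for (p in cohort) {
    for (b in seq_along(p$bouts)) {
      bt <- p$bouts[[b]]
      ft <- featurize_trial(bt$series, cfg)
      lab <- match_truth(ft$features, bt$truth, cfg$matching$tolerance_frames)
      if (nrow(lab) > 0) {
        lab$participant <- p$participant_id
        lab$bout <- b
        rows[[length(rows) + 1]] <- lab
      }
      if (keep_trials) {
        st <- match_truth(ft$strides, bt$truth, cfg$matching$tolerance_frames)
        trials[[length(trials) + 1]] <- list(kin = ft$kin, strides = st,
                                             participant = p$participant_id)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trials") <- if (keep_trials) trials else NULL
  out
}

#' Detected-versus-truth event timing over a cohort
#'
#' Runs segmentation on each bout and compares detected toe-off and
#' heel-contact frames against the generator's ground truth with
#' [bland_altman_timing()].
#'
#' @param cohort Result of [simulate_cohort()].
#' @param config A [pipeline_config()] or list of overrides.
#' @return List with `toe_off` and `heel_contact` Bland-Altman summaries.
#' @export
event_timing_validation <- function(cohort, config = NULL) {
  cfg <- as_config(config)
  to_d <- to_r <- hc_d <- hc_r <- list()
  offset <- 0
  for (p in cohort) {
    for (bt in p$bouts) {
      series <- to_participant_frame(bt$series)
      kin <- compute_foot_signals(series, cfg)
      to <- detect_toe_off(kin, cfg)
      hc <- detect_heel_contact(kin, to, cfg)
      to_d[[length(to_d) + 1]] <- to + offset
      to_r[[length(to_r) + 1]] <- bt$truth$to_truth + offset
      hc_d[[length(hc_d) + 1]] <- hc[!is.na(hc)] + offset
      hc_r[[length(hc_r) + 1]] <- bt$truth$hc_truth + offset
      offset <- offset + n_frames(series) + 1000  # keep bouts unmatchable
    }
  }
  fs <- cohort[[1]]$bouts[[1]]$series$sample_rate
  tol <- cfg$matching$tolerance_frames
  list(
    toe_off = bland_altman_timing(unlist(to_d), unlist(to_r), fs, tol),
    heel_contact = bland_altman_timing(unlist(hc_d), unlist(hc_r), fs, tol)
  )
}

#' Run one pipeline stage file-to-file
#'
#' Thin command dispatcher backing the `icegait` command-line script. Each
#' stage reads and writes plain files (CSV/JSON) so stages compose. A
#' manifest (effective config, seed, package version) is written next to
#' each output.
#'
#' @param command One of `"simulate"`, `"segment"`, `"featurize"`,
#'   `"train"`, `"predict"`, `"evaluate"`.
#' @param args Named list of stage arguments: `input` (path), `out` (path),
#'   `seed`, plus stage-specifics (`participants`, `steps` for simulate;
#'   `labels` for train/evaluate; `model` for predict).
#' @param config A [pipeline_config()] or list of overrides.
#' @return Invisibly, the main output path.
#' @export
run_pipeline <- function(command, args = list(), config = NULL) {
  cfg <- as_config(config)
  known <- c("simulate", "segment", "featurize", "train", "predict", "evaluate")
  if (!command %in% known) {
    stop("unknown command '", command, "'; expected one of: ",
         paste(known, collapse = ", "))
  }
  seed <- if (is.null(args$seed)) 1L else as.integer(args$seed)
  out <- args$out
  if (is.null(out)) stop("argument 'out' is required")
  need_input <- command %in% c("segment", "featurize", "train", "predict", "evaluate")
  if (need_input && is.null(args$input)) stop("argument 'input' is required")
  if (need_input && !file.exists(args$input)) {
    stop("stage input not found: ", args$input)
  }

  if (command == "simulate") {
    n_p <- if (is.null(args$participants)) 9L else as.integer(args$participants)
    n_s <- if (is.null(args$steps)) 200L else as.integer(args$steps)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    cohort <- simulate_cohort(n_p, n_s, seed = seed)
    truth_all <- list()
    for (p in cohort) {
      for (b in seq_along(p$bouts)) {
        bt <- p$bouts[[b]]
        base <- file.path(out, sprintf("%s_bout%02d", p$participant_id, b))
        write_trajectories(bt$series, paste0(base, ".csv"),
                           metadata = paste0(base, ".yaml"))
        tr <- bt$truth
        tr$participant <- p$participant_id; tr$bout <- b
        truth_all[[length(truth_all) + 1]] <- tr
      }
    }
    write.csv(do.call(rbind, truth_all), file.path(out, "ground_truth.csv"),
              row.names = FALSE)
    write_manifest(file.path(out, "manifest.json"), command, cfg, seed)
    return(invisible(out))
  }

  if (command %in% c("segment", "featurize")) {
    series <- read_trajectories(args$input, metadata = args$metadata)
    ft <- featurize_trial(series, cfg)
    if (command == "segment") {
      jsonlite::write_json(list(
        toe_offs = ft$events$toe_offs,
        heel_contacts = ft$events$heel_contacts,
        strides = ft$strides
      ), out, auto_unbox = TRUE, digits = NA, na = "null")
    } else {
      write.csv(ft$features, out, row.names = FALSE)
    }
    write_manifest(paste0(out, ".manifest.json"), command, cfg, seed)
    return(invisible(out))
  }

  if (command == "train") {
    data <- read.csv(args$input)
    models <- list(
      toe = train_slip_model(data, "toe", cfg, seed = seed),
      heel = train_slip_model(data, "heel", cfg, seed = seed)
    )
    save_slip_models(models, out)
    write_manifest(paste0(out, ".manifest.json"), command, cfg, seed)
    return(invisible(out))
  }

  if (command == "predict") {
    if (is.null(args$model)) stop("argument 'model' is required")
    models <- load_slip_models(args$model)
    feats <- read.csv(args$input)
    pred <- predict_steps(models, feats)
    write.csv(cbind(feats[, intersect(c("stride_id", "participant"), names(feats)),
                          drop = FALSE], pred), out, row.names = FALSE)
    return(invisible(out))
  }

  # evaluate: LOSOCV over a labelled feature table
  data <- read.csv(args$input)
  ev <- losocv(data, cfg, seed = seed)
  jsonlite::write_json(list(
    summary = ev$summary, overall = ev$overall_summary,
    folds = ev$folds, seed = seed
  ), out, auto_unbox = TRUE, digits = NA, na = "null")
  write_manifest(paste0(out, ".manifest.json"), command, cfg, seed)
  invisible(out)
}

write_manifest <- function(path, command, cfg, seed) {
  jsonlite::write_json(list(
    command = command, seed = seed,
    package_version = as.character(utils::packageVersion("icegait")),
    config = unclass(cfg), timestamp = format(Sys.time(), tz = "UTC")
  ), path, auto_unbox = TRUE, digits = NA)
}
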