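TAXONOMIES <- list(
  toe = list(classes = c("NTS", "BTS", "FTS"), no_slip = "NTS", column = "toe_class"),
  heel = list(classes = c("NHS", "BHS", "FHS"), no_slip = "NHS", column = "heel_class")
)

#' Derive the binary slip flag from the two taxonomy labels
#'
#' A step is a slip when it carries any of the four slip labels: backward or
#' forward toe slip, backward or forward heel slip (inclusive-or). Only a
#' step labelled both "no toe slip" and "no heel slip" is a non-slip.
#'
#' @param toe_class `"NTS"`, `"BTS"` or `"FTS"` (vectorised).
#' @param heel_class `"NHS"`, `"BHS"` or `"FHS"` (vectorised).
#' @return Logical vector.
#' @export
slip_flag <- function(toe_class, heel_class) {
  toe_class != "NTS" | heel_class != "NHS"
}

#' Fit-and-apply z-score normalization
#'
#' Normalization parameters (mean, SD per column) are fitted on the training
#' table only and applied to both tables. Zero-variance columns map to 0.
#'
#' @param train Numeric matrix/data.frame (training rows).
#' @param apply_to Optional second table with the same columns.
#' @return List with `train`, `apply_to` (normalized matrices), `center`,
#'   `scale`.
#' @export
normalize_fit_apply <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0) stop("training table is empty")
  if (!is.null(apply_to)) {
    apply_to <- as.matrix(apply_to)
    missing_cols <- setdiff(colnames(train), colnames(apply_to))
    if (length(missing_cols)) {
      stop("columns absent from apply_to: ", paste(missing_cols, collapse = ", "))
    }
    apply_to <- apply_to[, colnames(train), drop = FALSE]
  }
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- Inf  # zero-variance -> all zeros
  norm <- function(m) sweep(sweep(m, 2, ctr), 2, scl, "/")
  list(train = norm(train),
       apply_to = if (is.null(apply_to)) NULL else norm(apply_to),
       center = ctr, scale = scl)
}

# Fit one binary linear SVM (class vs rest) and reduce it to an explicit
# weight vector, intercept and Platt sigmoid calibrated on the training
# decision values. Orientation is fixed so the positive class has the larger
# mean decision value.
fit_binary_linear_svm <- function(x, positive, C) {
  yb <- factor(ifelse(positive, "pos", "rest"), levels = c("pos", "rest"))
  m <- e1071::svm(x, yb, kernel = "linear", cost = C, scale = FALSE)
  w <- as.numeric(crossprod(m$coefs, m$SV))
  b <- -m$rho
  dv <- as.numeric(x %*% w) + b
  if (mean(dv[positive]) < mean(dv[!positive])) {
    w <- -w; b <- -b; dv <- -dv
  }
  pl <- suppressWarnings(glm(positive ~ dv, family = binomial()))
  cf <- coef(pl)
  if (any(!is.finite(cf))) cf <- c(0, 1)
  list(w = w, b = b, platt = unname(cf))
}

binary_score <- function(fit, x, score = "platt") {
  dv <- as.numeric(x %*% fit$w) + fit$b
  if (score == "margin") dv else plogis(fit$platt[1] + fit$platt[2] * dv)
}

#' Train a 3-class one-vs-rest linear SVM
#'
#' One binary linear SVM per class (class vs rest). Each binary classifier
#' yields a probability-like score -- a Platt sigmoid fitted on the training
#' decision values (or the raw margin when `score = "margin"`) -- and
#' prediction takes the class with the largest score, breaking exact ties in
#' favour of the no-slip class.
#'
#' @param x Normalized feature matrix.
#' @param labels Class labels (3 classes, each with >= 2 samples).
#' @param C SVM cost parameter.
#' @param no_slip Name of the no-slip class (tie-break winner).
#' @param score `"platt"` or `"margin"`.
#' @return Object of class `"ovr_svm"` with per-class weight vectors,
#'   intercepts and Platt coefficients.
#' @export
train_ovr_linear_svm <- function(x, labels, C = 1, no_slip = NULL,
                                 score = "platt") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2) stop("single-class input: cannot train a classifier")
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("each class needs >= 2 samples; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  cls <- sort(cls)
  fits <- lapply(cls, function(cl) fit_binary_linear_svm(x, labels == cl, C))
  names(fits) <- cls
  out <- list(classes = cls, fits = fits, C = C,
              no_slip = if (is.null(no_slip)) cls[1] else no_slip,
              score = score, n_features = ncol(x),
              feature_names = colnames(x))
  class(out) <- "ovr_svm"
  out
}

#' Predict classes with a one-vs-rest model
#'
#' @param model An `"ovr_svm"` from [train_ovr_linear_svm()].
#' @param x Normalized feature matrix.
#' @return Character vector of predicted classes; attribute `"scores"` holds
#'   the per-class score matrix.
#' @export
predict_ovr <- function(model, x) {
  x <- as.matrix(x)
  scores <- vapply(model$classes,
                   function(cl) binary_score(model$fits[[cl]], x, model$score),
                   numeric(nrow(x)))
  if (nrow(x) == 1) scores <- matrix(scores, 1, dimnames = list(NULL, model$classes))
  pred <- apply(scores, 1, function(s) {
    top <- which(s == max(s))
    if (length(top) > 1 && model$no_slip %in% model$classes[top]) {
      model$no_slip
    } else {
      model$classes[top[1]]
    }
  })
  attr(pred, "scores") <- scores
  pred
}

#' Random under-sampling of the no-slip majority class
#'
#' Keeps every slip step and randomly down-samples the no-slip class so its
#' count equals the total slip count (when the no-slip class is already the
#' smaller group, everything is kept). Deterministic given `(seed,
#' repeat_index)`: the RNG is seeded with `seed + repeat_index`.
#'
#' @param labels Class labels.
#' @param no_slip Name of the majority (no-slip) class.
#' @param seed Base seed.
#' @param repeat_index Repeat number (1-based).
#' @return Integer row indices of the balanced subset, in increasing order.
#' @export
undersample <- function(labels, no_slip, seed = 1, repeat_index = 1) {
  labels <- as.character(labels)
  idx_no <- which(labels == no_slip)
  idx_slip <- which(labels != no_slip)
  n_target <- length(idx_slip)
  if (length(idx_no) <= n_target || n_target == 0) {
    return(sort(c(idx_no, idx_slip)))
  }
  old <- local_seed(seed + repeat_index)
  on.exit(restore_seed(old))
  sort(c(sample(idx_no, n_target), idx_slip))
}

# seed helpers: scoped RNG so library calls do not perturb user RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# stratified train/validation split; stratum = class x participant
split_train_validation <- function(labels, participants, fraction = 0.2, seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  strata <- interaction(labels, participants, drop = TRUE)
  val <- logical(length(labels))
  for (st in levels(strata)) {
    idx <- which(strata == st)
    n_val <- round(length(idx) * fraction)
    if (n_val > 0 && length(idx) > 1) {
      val[sample(idx, min(n_val, length(idx) - 1))] <- TRUE
    }
  }
  list(train = which(!val), validation = which(val))
}

#' Train a slip model for one taxonomy
#'
#' Applies the full training recipe to a feature table: under-sample the
#' no-slip class, split 80:20 into training and validation (stratified by
#' class and participant), tune the SVM cost on the validation macro-F1 over
#' the configured grid, then fit the one-vs-rest model with the winning cost
#' on the training split. Normalization is fitted on the training split
#' only.
#'
#' @param data data.frame with feature columns `f1`..`f36`, a `participant`
#'   column and the taxonomy label column (`toe_class` / `heel_class`).
#' @param taxonomy `"toe"` or `"heel"`.
#' @param config A [pipeline_config()] or list of overrides.
#' @param seed Seed for the under-sampling and the split.
#' @param repeat_index Under-sampling repeat (default 1).
#' @param C Optional fixed cost; skips tuning.
#' @return Object of class `"slip_model"`: the `"ovr_svm"`, normalization
#'   parameters, selected feature ids, taxonomy, tuned `C` and seeds.
#' @export
train_slip_model <- function(data, taxonomy = c("toe", "heel"), config = NULL,
                             seed = 1, repeat_index = 1, C = NULL) {
  taxonomy <- match.arg(taxonomy)
  cfg <- as_config(config)
  tx <- TAXONOMIES[[taxonomy]]
  feats <- paste0("f", selected_features(taxonomy))
  labels <- as.character(data[[tx$column]])
  part <- if ("participant" %in% names(data)) data$participant else rep(1, nrow(data))

  us <- undersample(labels, tx$no_slip, seed = seed, repeat_index = repeat_index)
  xs <- as.matrix(data[us, feats, drop = FALSE])
  ys <- labels[us]
  ps <- part[us]
  spl <- split_train_validation(ys, ps, fraction = cfg$classifier$validation_fraction,
                                seed = seed + 10000 * repeat_index)
  x_tr <- xs[spl$train, , drop = FALSE]; y_tr <- ys[spl$train]
  x_va <- xs[spl$validation, , drop = FALSE]; y_va <- ys[spl$validation]
  nrm <- normalize_fit_apply(x_tr, x_va)

  if (is.null(C)) {
    grid <- cfg$classifier$c_grid
    f1s <- vapply(grid, function(Ci) {
      m <- train_ovr_linear_svm(nrm$train, y_tr, C = Ci, no_slip = tx$no_slip,
                                score = cfg$classifier$score)
      macro_f1(predict_ovr(m, nrm$apply_to), y_va, tx$classes)
    }, numeric(1))
    C <- grid[which.max(f1s)]  # earliest (smallest C) wins ties
  }
  model <- train_ovr_linear_svm(nrm$train, y_tr, C = C, no_slip = tx$no_slip,
                                score = cfg$classifier$score)
  out <- list(model = model, center = nrm$center, scale = nrm$scale,
              feature_ids = selected_features(taxonomy),
              feature_names = feats, taxonomy = taxonomy, C = C,
              seed = seed, repeat_index = repeat_index,
              n_train = nrow(x_tr))
  class(out) <- "slip_model"
  out
}

#' @export
print.slip_model <- function(x, ...) {
  cat(sprintf("<slip_model> %s taxonomy, %d features, C = %g, n_train = %d\n",
              x$taxonomy, length(x$feature_ids), x$C, x$n_train))
  invisible(x)
}

# apply stored normalization and predict
predict_slip_model <- function(sm, data) {
  x <- as.matrix(data[, sm$feature_names, drop = FALSE])
  x <- sweep(sweep(x, 2, sm$center), 2, sm$scale, "/")
  predict_ovr(sm$model, x)
}

#' Predict step labels with a pair of trained slip models
#'
#' Runs the toe-slip and heel-slip classifiers on a feature table and
#' derives the binary slip flag as the inclusive-or of the four slip
#' classes.
#'
#' @param models List with elements `toe` and `heel`, each a `"slip_model"`.
#' @param features data.frame with feature columns `f1`..`f36`.
#' @return data.frame with `toe_class`, `heel_class`, `slip`.
#' @export
predict_steps <- function(models, features) {
  toe <- as.character(predict_slip_model(models$toe, features))
  heel <- as.character(predict_slip_model(models$heel, features))
  data.frame(toe_class = toe, heel_class = heel,
             slip = slip_flag(toe, heel))
}

#' Serialize a slip model (pair) to JSON
#'
#' The stored representation is plain text: per-class weight vectors,
#' intercepts, Platt coefficients, normalization parameters, feature ids and
#' seeds.
#'
#' @param models List with `toe` and `heel` slip models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_slip_models <- function(models, path) {
  ser <- lapply(models[c("toe", "heel")], function(sm) {
    list(taxonomy = sm$taxonomy, feature_ids = sm$feature_ids,
         feature_names = sm$feature_names,
         center = as.list(sm$center), scale = as.list(sm$scale),
         C = sm$C, seed = sm$seed, repeat_index = sm$repeat_index,
         n_train = sm$n_train,
         score = sm$model$score, no_slip = sm$model$no_slip,
         classes = sm$model$classes,
         fits = lapply(sm$model$fits, function(f) {
           list(w = f$w, b = f$b, platt = f$platt)
         }))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load slip models saved by [save_slip_models()]
#'
#' @param path JSON path.
#' @return List with `toe` and `heel` slip models.
#' @export
load_slip_models <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(ser, function(s) {
    fits <- lapply(s$fits, function(f) {
      list(w = as.numeric(f$w), b = as.numeric(f$b), platt = as.numeric(f$platt))
    })
    model <- list(classes = as.character(s$classes), fits = fits, C = s$C,
                  no_slip = s$no_slip, score = s$score,
                  n_features = length(s$feature_names),
                  feature_names = as.character(s$feature_names))
    class(model) <- "ovr_svm"
    sm <- list(model = model, center = unlist(s$center), scale = unlist(s$scale),
               feature_ids = as.integer(s$feature_ids),
               feature_names = as.character(s$feature_names),
               taxonomy = s$taxonomy, C = s$C, seed = s$seed,
               repeat_index = s$repeat_index, n_train = s$n_train)
    class(sm) <- "slip_model"
    sm
  })
}
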