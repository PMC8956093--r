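# Test helpers: direct construction of kinematics objects and independent
# brute-force oracles.

# Build a foot_kinematics object straight from signal vectors (bypassing
# filtering/differentiation), for unit tests of event/feature operations.
make_kin <- function(n, heel_ap_vel = 0, heel_vert_vel = 0, toe_ap_vel = 0,
                     toe_vert_vel = 0, heel_ml_vel = 0, foot_angle = 6.84,
                     heel_vert_pos = NULL, fs = 150) {
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  ha <- rep_n(heel_ap_vel); hv <- rep_n(heel_vert_vel)
  ta <- rep_n(toe_ap_vel); tv <- rep_n(toe_vert_vel)
  hm <- rep_n(heel_ml_vel); ang <- rep_n(foot_angle)
  ctz <- function(v) c(0, cumsum((v[-1] + v[-length(v)]) / 2)) / fs
  hz <- if (is.null(heel_vert_pos)) ctz(hv) else rep_n(heel_vert_pos)
  kin <- list(
    heel_pos = cbind(ap = ctz(ha), ml = ctz(hm), vert = hz),
    toe_pos = cbind(ap = ctz(ta) + 0.25, ml = ctz(hm), vert = ctz(tv) + 0.03),
    heel_vel = cbind(ap = ha, ml = hm, vert = hv),
    toe_vel = cbind(ap = ta, ml = hm, vert = tv),
    heel_acc_ap = differentiate_signal(ha, fs),
    foot_angle = ang,
    foot_angular_vel = differentiate_signal(ang, fs),
    sample_rate = fs,
    heel_marker = "heel", toe_marker = "toe"
  )
  class(kin) <- "foot_kinematics"
  kin
}

# O(n^2) brute-force peak scan: independent of find_peaks() internals.
naive_peaks <- function(x, min_height = -Inf, min_separation = 0,
                        min_prominence = 0) {
  n <- length(x)
  cand <- c()
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) cand <- c(cand, i)
  }
  ok <- c()
  for (p in cand) {
    if (x[p] < min_height) next
    lo_l <- x[p]
    i <- p - 1
    while (i >= 1 && x[i] <= x[p]) { lo_l <- min(lo_l, x[i]); i <- i - 1 }
    lo_r <- x[p]
    i <- p + 1
    while (i <= n && x[i] <= x[p]) { lo_r <- min(lo_r, x[i]); i <- i + 1 }
    if (x[p] - max(lo_l, lo_r) >= min_prominence) ok <- c(ok, p)
  }
  if (is.null(ok)) return(integer(0))
  kept <- c()
  for (p in ok[order(-x[ok], ok)]) {
    if (min_separation == 0 || !length(kept) ||
        all(abs(p - kept) >= min_separation)) {
      kept <- c(kept, p)
    }
  }
  sort(kept)
}

# small labelled feature table for classifier unit tests: three linearly
# separable blobs placed in features 5 and 10 (which both classifier
# subsets use), padded to f1..f36
make_blob_data <- function(n_per_class = 30, n_participants = 3, sep = 6,
                           seed = 1, noise = 1) {
  set.seed(seed)
  centers <- list(NTS = c(0, 0), BTS = c(sep, 0), FTS = c(0, sep))
  rows <- list()
  for (cl in names(centers)) {
    x <- cbind(rnorm(n_per_class, centers[[cl]][1], noise),
               rnorm(n_per_class, centers[[cl]][2], noise))
    rows[[cl]] <- data.frame(
      toe_class = cl,
      heel_class = "NHS",
      participant = rep_len(paste0("P", seq_len(n_participants)), n_per_class),
      f5 = x[, 1], f10 = x[, 2]
    )
  }
  out <- do.call(rbind, rows)
  for (k in setdiff(1:36, c(5, 10))) out[[paste0("f", k)]] <- rnorm(nrow(out), sd = 0.01)
  rownames(out) <- NULL
  out
}
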