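#' Zero-lag dual-pass Butterworth filter
#'
#' Low-pass filters a signal forward and backward so the net phase lag is
#' zero. The conventional "fourth-order, zero-lag, dual-pass" biomechanics
#' filter is obtained by designing a second-order Butterworth filter and
#' applying it in both directions (the default); set `order_per_pass = TRUE`
#' to design the full order per pass instead. Edge transients are suppressed
#' by reflective padding of length three times the filter order.
#'
#' @param x Numeric signal.
#' @param cutoff_hz Cut-off frequency in Hz; must be below Nyquist.
#' @param sample_rate Sampling rate in Hz.
#' @param order Effective filter order (default 4).
#' @param order_per_pass If `TRUE`, design `order` poles per pass.
#' @return Filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 150)
#' noisy <- sin(2 * pi * 2 * t) + 0.2 * sin(2 * pi * 60 * t)
#' smooth <- butterworth_zero_lag(noisy, 12, 150)
#' @export
butterworth_zero_lag <- function(x, cutoff_hz = 12, sample_rate = 150,
                                 order = 4, order_per_pass = FALSE) {
  if (cutoff_hz >= sample_rate / 2) {
    stop("cutoff_hz (", cutoff_hz, ") must be below Nyquist (", sample_rate / 2, " Hz)")
  }
  pad <- 3L * as.integer(order)
  if (length(x) <= pad + 1L) {
    stop("signal too short to filter: length ", length(x),
         " <= warm-up length ", pad + 1L)
  }
  n_design <- if (order_per_pass) order else max(1L, as.integer(round(order / 2)))
  bf <- signal::butter(n_design, cutoff_hz / (sample_rate / 2), type = "low")
  # reflective padding about the end points; each pass removes the leading
  # value first so the zero-state start-up transient vanishes (a constant
  # signal passes through exactly)
  one_pass <- function(z) {
    as.numeric(signal::filter(bf, z - z[1])) + z[1]
  }
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - pad)]
  xp <- c(left, x, right)
  y <- rev(one_pass(rev(one_pass(xp))))
  y[(pad + 1L):(pad + length(x))]
}

#' Differentiate a sampled signal
#'
#' Central differences at interior samples and one-sided differences at the
#' ends, scaled by the sampling rate. Exact for linear signals everywhere and
#' for quadratics at interior samples.
#'
#' @param x Numeric signal of length >= 3.
#' @param sample_rate Sampling rate in Hz.
#' @return Derivative of `x`, same length.
#' @export
differentiate_signal <- function(x, sample_rate = 150) {
  n <- length(x)
  if (n < 3) stop("differentiate_signal needs at least 3 samples, got ", n)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * sample_rate
  d[n] <- (x[n] - x[n - 1]) * sample_rate
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * sample_rate / 2
  d
}

#' Derive foot kinematic signals from a marker series
#'
#' Filters the heel and toe marker positions, differentiates them to obtain
#' velocities and the heel AP acceleration, and computes the foot angle (the
#' angle of the heel-to-toe vector relative to the floor plane, in the
#' sagittal AP-vertical plane, degrees) and its angular velocity. Because the
#' toe marker sits higher on the shoe than the heel marker, the flat-foot
#' angle is a positive offset, not zero; it is preserved, never subtracted.
#'
#' @param series A [marker_series()] in the participant-centric frame.
#' @param config A [pipeline_config()] or named list of overrides.
#' @param toe Optional explicit toe marker name (default: most anterior toe).
#' @return An object of class `"foot_kinematics"`: matrices `heel_pos`,
#'   `toe_pos`, `heel_vel`, `toe_vel` (columns ap/ml/vert), vectors
#'   `heel_acc_ap`, `foot_angle` (deg), `foot_angular_vel` (deg/s), and
#'   `sample_rate`. All sequences share the input length.
#' @export
compute_foot_signals <- function(series, config = NULL, toe = NULL) {
  cfg <- as_config(config)
  roles <- foot_marker_roles(series, toe = toe)
  fs <- series$sample_rate
  filt <- function(m) {
    apply(m, 2, butterworth_zero_lag, cutoff_hz = cfg$filter$cutoff_hz,
          sample_rate = fs, order = cfg$filter$order,
          order_per_pass = cfg$filter$order_per_pass)
  }
  heel <- filt(series$markers[[roles$heel]])
  toe_m <- filt(series$markers[[roles$toe]])
  sep <- sqrt(rowSums((toe_m - heel)^2))
  if (median(sep) < 1e-3) {
    stop("heel and toe markers are coincident (median separation ",
         sprintf("%.4f m)", median(sep)))
  }
  heel_vel <- apply(heel, 2, differentiate_signal, sample_rate = fs)
  toe_vel <- apply(toe_m, 2, differentiate_signal, sample_rate = fs)
  colnames(heel_vel) <- colnames(toe_vel) <- c("ap", "ml", "vert")
  angle <- atan2(toe_m[, "vert"] - heel[, "vert"], toe_m[, "ap"] - heel[, "ap"]) * 180 / pi
  out <- list(
    heel_pos = heel, toe_pos = toe_m,
    heel_vel = heel_vel, toe_vel = toe_vel,
    heel_acc_ap = differentiate_signal(heel_vel[, "ap"], fs),
    foot_angle = angle,
    foot_angular_vel = differentiate_signal(angle, fs),
    sample_rate = fs,
    heel_marker = roles$heel, toe_marker = roles$toe
  )
  class(out) <- "foot_kinematics"
  out
}

#' @export
print.foot_kinematics <- function(x, ...) {
  cat(sprintf("<foot_kinematics> %d frames @ %g Hz (heel: %s, toe: %s)\n",
              nrow(x$heel_pos), x$sample_rate, x$heel_marker, x$toe_marker))
  invisible(x)
}
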