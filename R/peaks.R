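#' Detect local maxima with height, prominence and separation constraints
#'
#' Strict local maxima of `x` are filtered by minimum height and minimum
#' topographic prominence, then thinned greedily by descending height so that
#' no two retained peaks are closer than `min_separation` frames (ties broken
#' by the earlier frame). For troughs, pass `-x` and negate the heights.
#'
#' @param x Numeric signal.
#' @param min_height Minimum peak value (default: none).
#' @param min_separation Minimum distance between retained peaks, frames.
#' @param min_prominence Minimum prominence (default 0).
#' @return A data.frame with columns `frame` (1-based index into `x`),
#'   `height`, `prominence`, ordered by frame.
#' @export
find_peaks <- function(x, min_height = -Inf, min_separation = 0,
                       min_prominence = 0) {
  empty <- data.frame(frame = integer(0), height = numeric(0),
                      prominence = numeric(0))
  n <- length(x)
  if (n < 3) return(empty)
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  cand <- cand[x[cand] >= min_height]
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0) return(empty)
  if (min_separation > 0 && length(cand) > 1) {
    ord <- order(-x[cand], cand)
    accepted <- integer(0)
    acc_mask <- logical(length(cand))
    for (k in ord) {
      if (all(abs(cand[k] - accepted) >= min_separation)) {
        accepted <- c(accepted, cand[k])
        acc_mask[k] <- TRUE
      }
    }
    cand <- cand[acc_mask]; prom <- prom[acc_mask]
  }
  ord <- order(cand)
  data.frame(frame = cand[ord], height = x[cand][ord], prominence = prom[ord])
}

peak_prominence <- function(x, p) {
  v <- x[p]
  lo_l <- v
  for (i in seq(p - 1, 1)) {
    if (x[i] > v) break
    if (x[i] < lo_l) lo_l <- x[i]
  }
  lo_r <- v
  if (p < length(x)) {
    for (i in seq(p + 1, length(x))) {
      if (x[i] > v) break
      if (x[i] < lo_r) lo_r <- x[i]
    }
  }
  v - max(lo_l, lo_r)
}

#' Inventory of signal peaks with lobe widths and areas
#'
#' Finds local extrema of the requested polarity inside a window, applying a
#' minimum inter-peak distance given in milliseconds. Each retained peak is
#' annotated with its *lobe*: the run of same-sign signal between the
#' surrounding zero crossings. The lobe area is the trapezoidal integral of
#' the signal over the lobe (reported as a magnitude), the width is the lobe
#' duration in seconds. Peaks sharing a lobe share its `lobe_id`, so area
#' aggregations can deduplicate.
#'
#' @param x Numeric signal (full trace).
#' @param sample_rate Sampling rate, Hz.
#' @param window Integer vector of 1-based frame indices to search (a
#'   contiguous range). Empty windows yield an empty inventory.
#' @param polarity `"positive"` or `"negative"`.
#' @param min_separation_ms Minimum distance between retained peaks, ms.
#' @param min_prominence Noise floor: minimum peak prominence and minimum
#'   peak magnitude.
#' @return data.frame with columns `frame`, `height` (signed), `width_s`,
#'   `area` (magnitude), `lobe_id`, `lobe_start`, `lobe_end`.
#' @export
peak_inventory <- function(x, sample_rate, window = seq_along(x),
                           polarity = c("positive", "negative"),
                           min_separation_ms = 7, min_prominence = 0) {
  polarity <- match.arg(polarity)
  empty <- data.frame(frame = integer(0), height = numeric(0),
                      width_s = numeric(0), area = numeric(0),
                      lobe_id = integer(0), lobe_start = integer(0),
                      lobe_end = integer(0))
  if (length(window) == 0) return(empty)
  window <- window[window >= 1 & window <= length(x)]
  if (length(window) < 3) return(empty)
  w <- x[window]
  if (polarity == "negative") w <- -w
  sep <- max(1L, as.integer(round(min_separation_ms / 1000 * sample_rate)))
  # peaks must clear the floor in value as well as prominence, so shallow
  # filter-ringing bumps next to deep troughs are not counted
  pk <- find_peaks(w, min_height = min_prominence, min_separation = sep,
                   min_prominence = min_prominence)
  if (nrow(pk) == 0) return(empty)
  lobes <- sign_lobes(w)
  out <- lapply(seq_len(nrow(pk)), function(k) {
    f <- pk$frame[k]
    li <- which(lobes$start <= f & lobes$end >= f)
    if (length(li) == 0) return(NULL)
    li <- li[1]
    seg <- w[lobes$start[li]:lobes$end[li]]
    data.frame(
      frame = window[f],
      height = if (polarity == "negative") -pk$height[k] else pk$height[k],
      width_s = (lobes$end[li] - lobes$start[li]) / sample_rate,
      area = trapz_area(seg, sample_rate),
      lobe_id = li,
      lobe_start = window[lobes$start[li]],
      lobe_end = window[lobes$end[li]]
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

# maximal runs where the signal is positive; returns start/end indices
sign_lobes <- function(w) {
  pos <- w > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

trapz_area <- function(seg, sample_rate) {
  if (length(seg) < 2) return(0)
  sum((seg[-1] + seg[-length(seg)]) / 2) / sample_rate
}

# trapezoidal integral of x over 1-based index range (signed)
trapz_range <- function(x, from, to, sample_rate) {
  if (to <= from) return(0)
  seg <- x[from:to]
  sum((seg[-1] + seg[-length(seg)]) / 2) / sample_rate
}
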