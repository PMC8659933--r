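# Sliding-window segmentation of processed pairs, arm-swap augmentation,
# and the fourteen between-arm asymmetry features.

WINDOW_MIN_CHOICES <- c(15, 30, 45, 60, 90, 120)

#' Windowing configuration
#'
#' @param window_min Window length in minutes; one of 15, 30, 45, 60, 90,
#'   120 (600 to 4800 samples at the 0.67 Hz processed rate).
#' @param overlap_frac Fractional overlap between adjacent windows (0.2:
#'   the stride is 80% of the window length).
#' @param rate_hz Processed sampling rate, Hz.
#' @return An object of class `window_config` with the window length in
#'   samples as `L` and the stride as `stride`.
#' @export
window_config <- function(window_min = 60, overlap_frac = 0.2,
                          rate_hz = 32 / 48) {
  if (!window_min %in% WINDOW_MIN_CHOICES) {
    stopf("window_min must be one of %s",
          paste(WINDOW_MIN_CHOICES, collapse = ", "))
  }
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stopf("overlap_frac must lie in [0, 1)")
  }
  L <- as.integer(round(window_min * 60 * rate_hz))
  structure(
    list(window_min = window_min, overlap_frac = overlap_frac,
         rate_hz = rate_hz, L = L,
         stride = as.integer(round((1 - overlap_frac) * L))),
    class = "window_config")
}

new_window_set <- function(x, subject_id, label, start_s, rate_hz) {
  structure(
    list(x = x,
         meta = data.frame(subject_id = subject_id, label = label,
                           window_start_s = start_s,
                           stringsAsFactors = FALSE),
         rate_hz = rate_hz),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Window set: %d windows of 2 x %d samples (%d subjects)\n",
              dim(x$x)[1], dim(x$x)[3],
              length(unique(x$meta$subject_id))))
  invisible(x)
}

#' Segment a processed pair into overlapping windows
#'
#' Start indices are 1, 1 + stride, 1 + 2 stride, ... with stride
#' `round((1 - overlap_frac) * L)`; a trailing partial window is discarded.
#'
#' @param pair A `processed_pair`.
#' @param wcfg A [window_config()].
#' @return A `window_set`: array `x` of dimension (windows, 2 arms, L) plus
#'   per-window subject id, label and start time. A pair shorter than one
#'   window yields an empty set with a warning.
#' @export
make_windows <- function(pair, wcfg = window_config()) {
  stopifnot(inherits(pair, "processed_pair"))
  n <- length(pair$arm1)
  L <- wcfg$L
  if (n < L) {
    warnf("pair '%s' shorter than one %d-min window; no windows produced",
          pair$subject_id, wcfg$window_min)
    return(new_window_set(array(0, dim = c(0, 2, L)), character(0),
                          character(0), numeric(0), pair$rate_hz))
  }
  starts <- seq(1L, n - L + 1L, by = wcfg$stride)
  x <- array(0, dim = c(length(starts), 2, L))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + L - 1L)
    x[i, 1, ] <- pair$arm1[idx]
    x[i, 2, ] <- pair$arm2[idx]
  }
  new_window_set(x, rep(pair$subject_id, length(starts)),
                 rep(pair$label, length(starts)),
                 (starts - 1) / pair$rate_hz, pair$rate_hz)
}

#' Concatenate window sets
#'
#' @param sets List of `window_set` objects with equal window lengths.
#' @return A single combined `window_set`.
#' @export
bind_windows <- function(sets) {
  sets <- Filter(function(s) dim(s$x)[1] > 0, sets)
  if (length(sets) == 0) stopf("no non-empty window sets to bind")
  L <- dim(sets[[1]]$x)[3]
  x <- array(0, dim = c(sum(vapply(sets, function(s) dim(s$x)[1], 0L)), 2, L))
  meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  at <- 0
  for (s in sets) {
    k <- dim(s$x)[1]
    if (dim(s$x)[3] != L) stopf("window lengths differ between sets")
    x[at + seq_len(k), , ] <- s$x
    at <- at + k
  }
  structure(list(x = x, meta = meta, rate_hz = sets[[1]]$rate_hz),
            class = "window_set")
}

#' Swap the two arms of every window
#'
#' Exchanges the arm-1 and arm-2 channels; labels are unchanged. Used for
#' left/right augmentation so models cannot learn a side preference.
#'
#' @param ws A `window_set`.
#' @return The window set with channels exchanged.
#' @export
swap_arms <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  ws$x <- ws$x[, c(2, 1), , drop = FALSE]
  ws
}

FEATURE_NAMES <- c("mean1", "mean2", "median1", "median2", "sd1", "sd2",
                   "max1", "max2", "dmean", "dmedian", "dsd", "dmax",
                   "frac1_gt2", "frac2_gt1")

# Population standard deviation (divisor L); the windows are complete
# segments, not samples from a larger population of interest.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Extract the fourteen asymmetry features from each window
#'
#' Per arm: mean, median, standard deviation (population convention,
#' divisor L) and maximum; their arm1 - arm2 differences; and the fraction
#' of samples where one arm exceeds the other by at least `delta` (counts
#' divided by the window length in samples, hence in \[0, 1\]).
#'
#' @param ws A `window_set`.
#' @param delta Exceedance threshold in g (default 0.01); the comparison is
#'   the closed inequality `arm_i - arm_j >= delta`.
#' @return Data frame with the 14 feature columns plus `subject_id`,
#'   `label` and `window_start_s`.
#' @export
extract_features <- function(ws, delta = 0.01) {
  stopifnot(inherits(ws, "window_set"))
  n <- dim(ws$x)[1]
  L <- dim(ws$x)[3]
  if (L < 2) stopf("windows must contain at least 2 samples")
  out <- matrix(0, nrow = n, ncol = length(FEATURE_NAMES),
                dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n)) {
    a1 <- ws$x[i, 1, ]
    a2 <- ws$x[i, 2, ]
    s1 <- c(mean(a1), stats::median(a1), sd_pop(a1), max(a1))
    s2 <- c(mean(a2), stats::median(a2), sd_pop(a2), max(a2))
    out[i, ] <- c(s1[1], s2[1], s1[2], s2[2], s1[3], s2[3], s1[4], s2[4],
                  s1 - s2,
                  mean(a1 - a2 >= delta), mean(a2 - a1 >= delta))
  }
  cbind(as.data.frame(out), ws$meta)
}

#' Arm-swap image of a feature matrix
#'
#' Computes the features of the arm-swapped windows directly from the
#' original features: per-arm statistics exchange, difference features
#' negate, and the two exceedance fractions exchange. Used to augment
#' classical training sets without revisiting the raw windows.
#'
#' @param feats Data frame as returned by [extract_features()].
#' @return Data frame of the same shape.
#' @export
swap_features <- function(feats) {
  sw <- feats
  perm <- c(mean1 = "mean2", mean2 = "mean1", median1 = "median2",
            median2 = "median1", sd1 = "sd2", sd2 = "sd1",
            max1 = "max2", max2 = "max1",
            frac1_gt2 = "frac2_gt1", frac2_gt1 = "frac1_gt2")
  for (to in names(perm)) sw[[to]] <- feats[[perm[[to]]]]
  for (d in c("dmean", "dmedian", "dsd", "dmax")) sw[[d]] <- -feats[[d]]
  sw
}
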