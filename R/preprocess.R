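# Preprocessing chain for bilateral 32 Hz count streams:
# per-axis Butterworth high-pass -> vector magnitude -> moving-average
# smoothing -> decimation -> normalisation to g -> inter-arm sync
# alignment -> trailing-tail removal.

#' Preprocessing configuration
#'
#' Defaults follow the published chain: 5th-order Butterworth high-pass at
#' 3 Hz on each axis of the 32 Hz counts, Euclidean magnitude, moving
#' average over 96 samples, subsampling by 48 (0.67 Hz output), division by
#' 64 counts/g. Sync alignment and tail trimming operate on the processed
#' 0.67 Hz signals.
#'
#' @param hp_order High-pass filter order.
#' @param hp_cutoff_hz High-pass cutoff, Hz; must be below `fs_raw_hz / 2`.
#' @param fs_raw_hz Raw sampling rate, Hz.
#' @param ma_len Moving-average length, samples.
#' @param decim Decimation factor.
#' @param norm_counts Counts per g used for normalisation.
#' @param max_sync_shift_s Maximum inter-arm shift searched, seconds.
#' @param tail_threshold_g Magnitude below which a sample counts as
#'   no-motion for tail trimming, g.
#' @param tail_min_duration_min Minimum no-motion run length (minutes) that
#'   is treated as a removable tail.
#' @param zero_phase If `TRUE` use forward-backward (zero-phase) filtering;
#'   the default is a causal single pass, as a real-time device would run.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(hp_order = 5L, hp_cutoff_hz = 3, fs_raw_hz = 32,
                              ma_len = 96L, decim = 48L, norm_counts = 64,
                              max_sync_shift_s = 300, tail_threshold_g = 0.01,
                              tail_min_duration_min = 10,
                              zero_phase = FALSE) {
  if (ma_len < 1 || decim < 1) stopf("ma_len and decim must be positive")
  if (hp_cutoff_hz >= fs_raw_hz / 2) {
    stopf("hp_cutoff_hz must be below the Nyquist frequency")
  }
  structure(
    list(hp_order = as.integer(hp_order), hp_cutoff_hz = hp_cutoff_hz,
         fs_raw_hz = fs_raw_hz, ma_len = as.integer(ma_len),
         decim = as.integer(decim), norm_counts = norm_counts,
         max_sync_shift_s = max_sync_shift_s,
         tail_threshold_g = tail_threshold_g,
         tail_min_duration_min = tail_min_duration_min,
         zero_phase = zero_phase),
    class = "preprocess_config")
}

# Filter transient: the causal 5th-order high-pass at 3 Hz/32 Hz has its
# slowest pole pair at radius ~0.84, so a step decays below 1e-6 of its
# size only after ~100 samples; 4 s is a safe documented warm-up.
HP_WARMUP_S <- 4

#' Per-axis high-pass filter
#'
#' @param axis_signals Numeric matrix, one column per axis, at the raw rate.
#' @param cfg A [preprocess_config()].
#' @return Matrix of the same shape with the DC (gravity) component removed.
#' @export
highpass <- function(axis_signals, cfg = preprocess_config()) {
  x <- as.matrix(axis_signals)
  if (nrow(x) < cfg$fs_raw_hz) stopf("input shorter than 1 s")
  bf <- signal::butter(cfg$hp_order, cfg$hp_cutoff_hz / (cfg$fs_raw_hz / 2),
                       type = "high")
  apply(x, 2, function(col) {
    if (cfg$zero_phase) signal::filtfilt(bf, col)
    else as.numeric(signal::filter(bf, col))
  })
}

#' Euclidean magnitude of a triaxial signal
#'
#' @param filtered Matrix with three columns (x, y, z).
#' @return Non-negative numeric vector, `sqrt(x^2 + y^2 + z^2)` pointwise.
#' @export
magnitude <- function(filtered) {
  x <- as.matrix(filtered)
  if (ncol(x) != 3) stopf("expected three equal-length axis signals")
  sqrt(rowSums(x^2))
}

#' Smooth, decimate and normalise a magnitude signal
#'
#' Causal moving average over `ma_len` samples (expanding window over the
#' first `ma_len - 1` samples, so output length equals input length),
#' decimation keeping samples 1, 1 + decim, 1 + 2 decim, ..., then division
#' by `norm_counts` so a value of 1 equals gravity. A 15-min stretch of
#' 32 Hz input (28 800 samples) yields exactly 600 output samples at
#' 32/48 = 0.67 Hz.
#'
#' @param mag Non-negative magnitude series at the raw rate.
#' @param cfg A [preprocess_config()].
#' @return Numeric series at `fs_raw_hz / decim` Hz in g units, with the
#'   output rate attached as attribute `rate_hz`.
#' @export
smooth_decimate_normalize <- function(mag, cfg = preprocess_config()) {
  n <- length(mag)
  if (n < cfg$ma_len) stopf("input shorter than the moving-average window")
  cs <- cumsum(mag)
  m <- cfg$ma_len
  ma <- numeric(n)
  if (m > 1) ma[1:(m - 1)] <- cs[1:(m - 1)] / (1:(m - 1))
  ma[m:n] <- (cs[m:n] - c(0, cs[seq_len(n - m)])) / m
  out <- ma[seq(1, n, by = cfg$decim)] / cfg$norm_counts
  attr(out, "rate_hz") <- cfg$fs_raw_hz / cfg$decim
  out
}

#' Align the two arms' processed signals
#'
#' Exhaustively searches integer lags within `max_sync_shift_s` for the one
#' minimising the mean absolute difference between the two series on their
#' overlap (the mean, rather than the raw sum, so short overlaps are not
#' trivially favoured). A positive shift means `arm2`'s stream content lags
#' `arm1` by that many samples.
#'
#' @param arm1,arm2 Processed magnitude series at the decimated rate.
#' @param cfg A [preprocess_config()].
#' @param rate_hz Sampling rate of the inputs, Hz.
#' @return List with the overlap-cropped `arm1`, `arm2` (equal lengths) and
#'   the integer `shift` in samples.
#' @export
sync_align <- function(arm1, arm2, cfg = preprocess_config(),
                       rate_hz = cfg$fs_raw_hz / cfg$decim) {
  n1 <- length(arm1)
  n2 <- length(arm2)
  max_lag <- as.integer(round(cfg$max_sync_shift_s * rate_hz))
  if (min(n1, n2) <= max_lag) {
    stopf("series shorter than the maximum sync shift")
  }
  best <- NULL
  for (s in -max_lag:max_lag) {
    if (s >= 0) {
      len <- min(n1, n2 - s)
      if (len < 1) next
      d <- mean(abs(arm1[1:len] - arm2[(1 + s):(s + len)]))
    } else {
      len <- min(n1 + s, n2)
      if (len < 1) next
      d <- mean(abs(arm1[(1 - s):(len - s)] - arm2[1:len]))
    }
    # strict improvement keeps the smallest |lag| (scan order) on exact ties
    if (is.null(best) || d < best$d - 1e-15 ||
        (abs(d - best$d) <= 1e-15 && abs(s) < abs(best$s))) {
      best <- list(s = s, d = d, len = len)
    }
  }
  if (is.null(best)) stopf("empty overlap at all lags")
  s <- best$s
  len <- best$len
  if (s >= 0) {
    list(arm1 = arm1[1:len], arm2 = arm2[(1 + s):(s + len)], shift = s)
  } else {
    list(arm1 = arm1[(1 - s):(len - s)], arm2 = arm2[1:len], shift = s)
  }
}

#' Remove the trailing no-motion tail
#'
#' Finds the maximal trailing run where both arms stay below
#' `tail_threshold_g`; if it lasts at least `tail_min_duration_min` minutes
#' it is removed (bracelets left running after the session ends record such
#' tails). A recording that is quiet throughout is rejected.
#'
#' @param pair A `processed_pair` (see [preprocess_recording()]).
#' @param cfg A [preprocess_config()].
#' @return The pair, possibly shortened.
#' @export
trim_tails <- function(pair, cfg = preprocess_config()) {
  stopifnot(inherits(pair, "processed_pair"))
  quiet <- pair$arm1 < cfg$tail_threshold_g & pair$arm2 < cfg$tail_threshold_g
  n <- length(quiet)
  k <- 0
  while (k < n && quiet[n - k]) k <- k + 1
  if (k == n) stopf("empty after trimming: recording has no movement")
  if (k / pair$rate_hz / 60 >= cfg$tail_min_duration_min) {
    pair$arm1 <- pair$arm1[1:(n - k)]
    pair$arm2 <- pair$arm2[1:(n - k)]
  }
  pair
}

new_processed_pair <- function(arm1, arm2, rate_hz, shift, subject_id,
                               label, paresis_grade = NA_integer_,
                               affected_side = NA_character_) {
  structure(
    list(arm1 = as.numeric(arm1), arm2 = as.numeric(arm2),
         rate_hz = rate_hz, shift = as.integer(shift),
         subject_id = subject_id, label = label,
         paresis_grade = paresis_grade, affected_side = affected_side),
    class = "processed_pair")
}

#' @export
print.processed_pair <- function(x, ...) {
  cat(sprintf(
    "Processed pair '%s' (%s): %d samples @ %.2f Hz (%.2f h), sync shift %d\n",
    x$subject_id, x$label, length(x$arm1), x$rate_hz,
    length(x$arm1) / x$rate_hz / 3600, x$shift))
  invisible(x)
}

#' Run the full preprocessing chain on a raw recording
#'
#' Composition of [highpass()], [magnitude()] and
#' [smooth_decimate_normalize()] per arm, then [sync_align()] and
#' [trim_tails()]. The first 4 s of each processed channel (the causal
#' filter's start-up transient) are discarded.
#'
#' @param rec A `raw_recording` (see [simulate_subject()] / [read_recording()]).
#' @param cfg A [preprocess_config()].
#' @return An object of class `processed_pair`: two aligned non-negative
#'   magnitude channels in g units at `fs_raw_hz / decim` Hz.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  # drop the filter's start-up transient from the processed series
  wu <- ceiling(HP_WARMUP_S * cfg$fs_raw_hz / cfg$decim)
  chans <- lapply(list(rec$arm1, rec$arm2), function(a) {
    out <- smooth_decimate_normalize(magnitude(highpass(a, cfg)), cfg)
    out[-seq_len(wu)]
  })
  al <- sync_align(chans[[1]], chans[[2]], cfg)
  pair <- new_processed_pair(
    al$arm1, al$arm2, rate_hz = cfg$fs_raw_hz / cfg$decim, shift = al$shift,
    subject_id = rec$subject_id, label = rec$group,
    paresis_grade = rec$paresis_grade, affected_side = rec$affected_side)
  trim_tails(pair, cfg)
}
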