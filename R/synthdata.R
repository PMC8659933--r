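# Synthetic bilateral wrist accelerometry.
#
# The generator emulates what the analysis chain assumes about real
# recordings: an 8-bit triaxial sensor at 32 Hz on each wrist (64 counts per
# g), a gravity baseline that reorients when the arm moves, sparse
# band-limited activity bouts shared between the arms, a nightly sleep
# window with rare small bouts, per-bracelet start-time offsets, and a
# trailing no-motion "tail" before the bracelets are switched off. Paresis
# is modelled as a grade-dependent attenuation of the affected arm's bout
# amplitudes, with grade 4 ("no movement") fully attenuated.

#' Subject profile for the simulator
#'
#' @param subject_id Character id.
#' @param group `"stroke"` or `"control"`.
#' @param paresis_grade Integer 0-4 on the arm-motor (NIHSS item 5) scale;
#'   0 for controls, 1-4 for stroke subjects (4 = no movement).
#' @param affected_side `"left"`, `"right"`, or `"none"` (controls).
#' @param activity_level Mean waking bout peak amplitude in g.
#' @param sleep_window Numeric length-2, start and end hour of the nightly
#'   sleep window (may wrap midnight).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            group = c("control", "stroke"),
                            paresis_grade = 0L,
                            affected_side = c("none", "left", "right"),
                            activity_level = 1.0,
                            sleep_window = c(23, 7)) {
  group <- match.arg(group)
  affected_side <- match.arg(affected_side)
  paresis_grade <- as.integer(paresis_grade)
  if (group == "control" && (paresis_grade != 0L || affected_side != "none")) {
    stopf("control subjects must have paresis_grade 0 and affected_side 'none'")
  }
  if (group == "stroke" &&
      (!paresis_grade %in% 1:4 || affected_side == "none")) {
    stopf("stroke subjects need paresis_grade in 1..4 and an affected side")
  }
  if (!is.numeric(activity_level) || activity_level <= 0) {
    stopf("activity_level must be a positive scalar (g)")
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         paresis_grade = paresis_grade, affected_side = affected_side,
         activity_level = activity_level, sleep_window = sleep_window),
    class = "subject_profile")
}

#' Simulator configuration
#'
#' @param duration_h Recording duration in hours (including the tail).
#' @param fs_raw Raw sampling rate, Hz.
#' @param counts_per_g Sensor counts per g (8-bit scale: 64).
#' @param start_offset_s Start-time offset of the second (right) bracelet
#'   relative to the first, seconds.
#' @param tail_min Minutes of trailing baseline-only data.
#' @param attenuation_by_grade Named vector mapping paresis grade 1-4 to a
#'   multiplier in \[0, 1\] on affected-arm bout amplitude; must be
#'   non-increasing with grade, and ~0 at grade 4.
#' @param noise_sd_counts Gaussian sensor noise SD, counts.
#' @param seed RNG seed.
#' @param start_hour Clock hour at which the recording starts.
#' @param wake_bout_rate_per_min,sleep_bout_rate_per_min Poisson bout
#'   arrival rates while awake / asleep.
#' @param bout_duration_s Median bout duration, seconds.
#' @param unilateral_frac Fraction of bouts affecting a single arm only.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_h = 24,
                       fs_raw = 32,
                       counts_per_g = 64,
                       start_offset_s = 0,
                       tail_min = 10,
                       attenuation_by_grade = c(`1` = 0.7, `2` = 0.4,
                                                `3` = 0.15, `4` = 0.0),
                       noise_sd_counts = 0.15,
                       seed = 1L,
                       start_hour = 12,
                       wake_bout_rate_per_min = 4,
                       sleep_bout_rate_per_min = 0.15,
                       bout_duration_s = 4,
                       unilateral_frac = 0.2) {
  if (!is.numeric(duration_h) || duration_h <= 0) {
    stopf("duration_h must be positive")
  }
  att <- attenuation_by_grade[as.character(1:4)]
  if (anyNA(att)) stopf("attenuation_by_grade must name grades 1..4")
  if (any(diff(att) > 1e-12)) {
    stopf("attenuation_by_grade must be non-increasing in grade")
  }
  if (att[["4"]] > 0.05) stopf("attenuation at grade 4 must be ~0")
  if (any(att < 0 | att > 1)) stopf("attenuation values must lie in [0, 1]")
  structure(
    list(duration_h = duration_h, fs_raw = fs_raw,
         counts_per_g = counts_per_g, start_offset_s = start_offset_s,
         tail_min = tail_min, attenuation_by_grade = att,
         noise_sd_counts = noise_sd_counts, seed = as.integer(seed),
         start_hour = start_hour,
         wake_bout_rate_per_min = wake_bout_rate_per_min,
         sleep_bout_rate_per_min = sleep_bout_rate_per_min,
         bout_duration_s = bout_duration_s,
         unilateral_frac = unilateral_frac),
    class = "sim_config")
}

is_asleep <- function(t_s, start_hour, sleep_window) {
  h <- (start_hour + t_s / 3600) %% 24
  ss <- sleep_window[1] %% 24
  se <- sleep_window[2] %% 24
  if (ss < se) h >= ss & h < se else h >= ss | h < se
}

rand_unit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Piecewise-linear gravity orientation: constant between reorientation
# events, 1 s linear ramp at each event.
orientation_track <- function(t_grid, t0, d0, events) {
  times <- t0
  vals <- matrix(d0, nrow = 1)
  if (length(events) > 0) {
    prev <- d0
    for (ev in events) {
      times <- c(times, ev$t, ev$t + 1)
      vals <- rbind(vals, prev, ev$d)
      prev <- ev$d
    }
  }
  out <- matrix(0, nrow = length(t_grid), ncol = 3)
  if (length(times) == 1) {
    return(matrix(d0, nrow = length(t_grid), ncol = 3, byrow = TRUE))
  }
  for (a in 1:3) {
    out[, a] <- stats::approx(times, vals[, a], xout = t_grid,
                              method = "linear", rule = 2)$y
  }
  out
}

#' Simulate one subject's bilateral recording
#'
#' Generates two 8-bit triaxial streams at the raw rate. Both arms share the
#' same Poisson bout process (a fraction of bouts is unilateral); the
#' affected arm's bout amplitudes are multiplied by the grade's attenuation
#' factor. Bouts are band-limited bursts (carrier 4-10 Hz under a Hann
#' envelope) so that all their energy survives the 3 Hz high-pass. The
#' gravity baseline reorients after sufficiently large bouts and is
#' otherwise static; the last `tail_min` minutes are baseline-only.
#'
#' @param profile A [subject_profile()].
#' @param cfg A [sim_config()].
#' @return An object of class `raw_recording` with integer matrices
#'   `arm1` (left) and `arm2` (right), start timestamps, sampling rate and
#'   the subject metadata.
#' @export
simulate_subject <- function(profile, cfg) {
  if (!inherits(profile, "subject_profile")) {
    profile <- do.call(subject_profile, profile)
  }
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  with_seed(cfg$seed, simulate_subject_impl(profile, cfg))
}

simulate_subject_impl <- function(profile, cfg) {
  fs <- cfg$fs_raw
  total_s <- cfg$duration_h * 3600
  n <- round(total_s * fs)
  active_end <- total_s - cfg$tail_min * 60
  if (active_end <= 0) stopf("tail_min leaves no active recording time")
  off <- cfg$start_offset_s

  # Shared bout process over world time, thinned by the sleep schedule.
  span_lo <- min(0, off)
  span_hi <- active_end + max(0, off)
  max_rate <- max(cfg$wake_bout_rate_per_min, cfg$sleep_bout_rate_per_min) / 60
  n_cand <- stats::rpois(1, max_rate * (span_hi - span_lo))
  cand_t <- sort(stats::runif(n_cand, span_lo, span_hi))
  asleep <- is_asleep(cand_t, cfg$start_hour, profile$sleep_window)
  rate_t <- ifelse(asleep, cfg$sleep_bout_rate_per_min,
                   cfg$wake_bout_rate_per_min) / 60
  keep <- stats::runif(n_cand) < rate_t / max_rate
  bt <- cand_t[keep]
  basleep <- asleep[keep]
  nb <- length(bt)

  bouts <- vector("list", nb)
  for (i in seq_len(nb)) {
    dur <- min(30, max(0.5, stats::rlnorm(1, log(cfg$bout_duration_s), 0.5)))
    amp <- profile$activity_level * stats::rlnorm(1, 0, 0.4)
    if (basleep[i]) amp <- amp * 0.4
    lat <- if (stats::runif(1) < cfg$unilateral_frac) {
      if (stats::runif(1) < 0.5) "arm1" else "arm2"
    } else {
      "both"
    }
    bouts[[i]] <- list(
      t = bt[i], dur = dur, amp = amp,
      freq = stats::runif(1, 4, 10), phase = stats::runif(1, 0, 2 * pi),
      dir = rand_unit3(), lat = lat,
      jit = exp(stats::rnorm(2, 0, 0.1)))
  }

  att <- 1
  affected <- 0L
  if (profile$group == "stroke") {
    att <- cfg$attenuation_by_grade[[as.character(profile$paresis_grade)]]
    affected <- if (profile$affected_side == "left") 1L else 2L
  }

  # hand dominance: the non-dominant arm moves mildly less in everyone,
  # so controls are not perfectly symmetric
  arm_gain <- c(1, 1)
  arm_gain[sample(1:2, 1)] <- stats::runif(1, 0.85, 1)

  arms <- vector("list", 2)
  for (arm in 1:2) {
    arm_off <- if (arm == 2) off else 0
    t_grid <- arm_off + (0:(n - 1)) / fs
    sig <- matrix(0, nrow = n, ncol = 3)
    events <- list()
    for (b in bouts) {
      if (b$lat != "both" && b$lat != paste0("arm", arm)) next
      a <- b$amp * b$jit[arm] * arm_gain[arm] *
        (if (arm == affected) att else 1)
      if (a <= 0) next
      i0 <- max(1L, ceiling((b$t - arm_off) * fs) + 1L)
      i1 <- min(n, floor((b$t + b$dur - arm_off) * fs) + 1L)
      if (i1 < i0) next
      tt <- t_grid[i0:i1] - b$t
      env <- sin(pi * tt / b$dur)^2
      wav <- a * cfg$counts_per_g * env *
        sin(2 * pi * b$freq * tt + b$phase)
      for (ax in 1:3) sig[i0:i1, ax] <- sig[i0:i1, ax] + wav * b$dir[ax]
      if (a > 0.05 && stats::runif(1) < 0.5) {
        events[[length(events) + 1]] <-
          list(t = b$t + b$dur, d = rand_unit3())
      }
    }
    grav <- orientation_track(t_grid, t_grid[1] - 1, rand_unit3(), events)
    sig <- sig + grav * cfg$counts_per_g +
      matrix(stats::rnorm(3 * n, 0, cfg$noise_sd_counts), ncol = 3)
    arms[[arm]] <- matrix(as.integer(pmin(127, pmax(-128, round(sig)))),
                          ncol = 3)
  }

  t0 <- 1.7e9 + cfg$start_hour * 3600
  structure(
    list(arm1 = arms[[1]], arm2 = arms[[2]], fs = fs,
         counts_per_g = cfg$counts_per_g,
         t0 = c(arm1 = t0, arm2 = t0 + off),
         subject_id = profile$subject_id, group = profile$group,
         paresis_grade = profile$paresis_grade,
         affected_side = profile$affected_side),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "Bilateral raw recording '%s' (%s%s)\n  %d samples/arm @ %g Hz (%.2f h), arm2 offset %+.1f s\n",
    x$subject_id, x$group,
    if (x$group == "stroke") {
      sprintf(", grade %d, %s side", x$paresis_grade, x$affected_side)
    } else "",
    nrow(x$arm1), x$fs, nrow(x$arm1) / x$fs / 3600,
    x$t0[["arm2"]] - x$t0[["arm1"]]))
  invisible(x)
}

# Cohort defaults mirror the study population: grade mix 1p 9.5%, 2p 25.0%,
# 3p 42.9%, 4p 22.6%; right-sided paresis with probability 0.452; monitoring
# times spread over about one hour above the nominal duration.
GRADE_PROBS <- c(`1` = 0.095, `2` = 0.250, `3` = 0.429, `4` = 0.226)
P_RIGHT_SIDE <- 0.452

#' Simulate a labeled cohort
#'
#' Draws per-subject paresis grades from the study's severity mix, affected
#' sides, monitoring durations and bracelet start offsets, then simulates
#' each subject. Per-subject seeds are derived from `cfg$seed` and the
#' subject id, so an existing cohort is unchanged when subjects are added.
#'
#' @param n_stroke,n_control Subject counts (>= 0).
#' @param cfg A [sim_config()]; `duration_h` is the minimum monitoring time,
#'   with per-subject durations drawn uniformly up to one hour longer.
#' @return List of `raw_recording` objects (labels carried inside each).
#' @export
simulate_cohort <- function(n_stroke, n_control, cfg = sim_config()) {
  if (n_stroke < 0 || n_control < 0) stopf("subject counts must be >= 0")
  recs <- vector("list", n_stroke + n_control)
  k <- 0
  for (grp in c("stroke", "control")) {
    n_g <- if (grp == "stroke") n_stroke else n_control
    for (i in seq_len(n_g)) {
      sid <- sprintf("%s%03d", if (grp == "stroke") "S" else "C", i)
      sseed <- derive_seed(cfg$seed, sid)
      rec <- with_seed(sseed, {
        grade <- if (grp == "stroke") {
          sample(1:4, 1, prob = GRADE_PROBS)
        } else 0L
        side <- if (grp == "stroke") {
          if (stats::runif(1) < P_RIGHT_SIDE) "right" else "left"
        } else "none"
        prof <- subject_profile(
          subject_id = sid, group = grp, paresis_grade = grade,
          affected_side = side,
          activity_level = exp(stats::rnorm(1, 0, 0.2)))
        scfg <- cfg
        scfg$duration_h <- cfg$duration_h + stats::runif(1, 0, 1)
        scfg$start_offset_s <- stats::runif(1, -30, 30)
        scfg$seed <- derive_seed(sseed, "signal")
        simulate_subject(prof, scfg)
      })
      k <- k + 1
      recs[[k]] <- rec
    }
  }
  recs
}
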