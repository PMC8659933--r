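warmup_n <- function(cfg = preprocess_config()) {
  round(armasym:::HP_WARMUP_S * cfg$fs_raw_hz)
}

test_that("the high-pass filter annihilates a constant gravity signal", {
  x <- matrix(rep(c(0, 0, 64), each = 32 * 60), ncol = 3)
  y <- highpass(x)
  expect_lt(max(abs(y[-(1:warmup_n()), ])), 1e-6)
})

test_that("filter magnitude response matches the analytic Butterworth gain", {
  fs <- 32
  t <- (0:(fs * 60 - 1)) / fs
  for (f in c(8, 0.5)) {
    y <- highpass(matrix(sin(2 * pi * f * t), ncol = 3, nrow = length(t)))
    amp <- fit_amplitude(y[-(1:(10 * fs)), 1], f, fs)
    expected <- butter_hp_gain(f, fc = 3, fs = fs, ord = 5)
    if (f == 8) {
      # passband: within 5% of unit gain
      expect_lt(abs(amp - 1), 0.05)
      expect_lt(abs(amp - expected) / expected, 0.01)
    } else {
      # deep stopband: at least 30 dB down, and matching the analytic curve
      expect_lt(amp, 10^(-30 / 20))
      expect_lt(abs(amp - expected) / expected, 0.05)
    }
  }
})

test_that("too-short input is rejected by the filter", {
  expect_error(highpass(matrix(0, nrow = 16, ncol = 3)), "shorter than 1 s")
})

test_that("magnitude is the pointwise Euclidean norm", {
  m <- magnitude(rbind(c(3, 4, 0), c(0, 0, 0), c(1, 1, 1)))
  expect_equal(m, c(5, 0, sqrt(3)))
  expect_error(magnitude(matrix(1, 2, 2)), "three")
})

test_that("smoothing/decimation/normalisation matches a brute-force oracle", {
  cfg <- preprocess_config()
  # constant input: averaging preserves constants, then /64
  const <- smooth_decimate_normalize(rep(32, 2000), cfg)
  expect_equal(as.numeric(const), rep(0.5, length(const)))

  # 15 min of 32 Hz input -> exactly 600 samples at 0.67 Hz
  out <- smooth_decimate_normalize(runif(28800), cfg)
  expect_length(out, 600)
  expect_equal(attr(out, "rate_hz"), 32 / 48)

  # impulse of height 96 * 64 -> exactly two nonzero outputs, each 1
  x <- numeric(96 * 40)
  x[1000] <- 96 * 64
  out <- smooth_decimate_normalize(x, cfg)
  nz <- which(out > 1e-12)
  expect_length(nz, 2)
  expect_equal(as.numeric(out[nz]), c(1, 1))

  # random lengths against the direct-convolution oracle
  for (n in c(96, 100, 500, 4321)) {
    x <- rlnorm(n)
    expect_equal(as.numeric(smooth_decimate_normalize(x, cfg)),
                 sdn_oracle(x), tolerance = 1e-12)
  }
  expect_error(smooth_decimate_normalize(rep(1, 95), cfg), "shorter")
})

test_that("output length is ceiling(n / decim) for any input length", {
  cfg <- preprocess_config()
  for (n in c(96, 97, 143, 144, 145, 28800, 28801)) {
    out <- smooth_decimate_normalize(numeric(n), cfg)
    expect_length(out, ceiling(n / 48))
  }
})

test_that("the chain is invariant to a constant gravity offset", {
  set.seed(1)
  x <- matrix(rnorm(3 * 32 * 30, sd = 5), ncol = 3)
  shifted <- sweep(x, 2, c(17, -64, 40), `+`)
  cfg <- preprocess_config()
  w <- ceiling(warmup_n() / cfg$decim) + 1
  a <- smooth_decimate_normalize(magnitude(highpass(x, cfg)), cfg)
  b <- smooth_decimate_normalize(magnitude(highpass(shifted, cfg)), cfg)
  expect_lt(max(abs(a[-(1:w)] - b[-(1:w)])), 1e-6)
})

test_that("sync alignment recovers injected shifts", {
  cfg <- preprocess_config(max_sync_shift_s = 30)
  set.seed(42)
  a <- rlnorm(2000, -2, 0.7)
  al <- sync_align(a, a, cfg, rate_hz = 2 / 3)
  expect_identical(al$shift, 0L)
  expect_equal(al$arm1, al$arm2)

  # arm2 delayed by 7 samples
  a2 <- c(rep(0.01, 7), a[1:(length(a) - 7)])
  al <- sync_align(a, a2, cfg, rate_hz = 2 / 3)
  expect_identical(al$shift, 7L)
  expect_equal(al$arm1, al$arm2)

  # independent noise: must equal the exhaustive-search argmin
  for (s in 1:5) {
    set.seed(s)
    x <- rlnorm(500, -2, 0.5)
    y <- rlnorm(500, -2, 0.5)
    ml <- round(30 * 2 / 3)
    expect_identical(sync_align(x, y, cfg, rate_hz = 2 / 3)$shift,
                     as.integer(sync_oracle(x, y, ml)))
  }
  expect_error(sync_align(rnorm(10), rnorm(10), preprocess_config()),
               "shorter")
})

test_that("tail trimming removes long quiet endings only", {
  cfg <- preprocess_config()
  rate <- 2 / 3
  active <- rep(0.5, 2400)
  quiet <- rep(0.001, round(30 * 60 * rate))   # 30 quiet minutes
  p <- make_pair(c(active, quiet), c(active, quiet))
  tr <- trim_tails(p, cfg)
  expect_length(tr$arm1, length(active))

  # active ending: unchanged
  p2 <- make_pair(rev(c(active, quiet)), rev(c(active, quiet)))
  expect_length(trim_tails(p2, cfg)$arm1, length(active) + length(quiet))

  # short quiet ending (below the minimum duration): unchanged
  shortq <- rep(0.001, round(5 * 60 * rate))
  p3 <- make_pair(c(active, shortq), c(active, shortq))
  expect_length(trim_tails(p3, cfg)$arm1, length(active) + length(shortq))

  # all-quiet recording: error
  p4 <- make_pair(rep(0.001, 4000), rep(0.001, 4000))
  expect_error(trim_tails(p4, cfg), "empty after trimming")
})

test_that("the full chain runs end to end on a simulated subject", {
  fix <- small_sim_cohort()
  pair <- fix$pairs[[which(vapply(fix$cohort, `[[`, "", "group") ==
                             "control")[1]]]
  expect_s3_class(pair, "processed_pair")
  expect_equal(round(pair$rate_hz, 2), 0.67)
  expect_true(all(pair$arm1 >= 0 & pair$arm2 >= 0))
  expect_true(all(pair$arm1 <= 2 & pair$arm2 <= 2))
  expect_length(pair$arm1, length(pair$arm2))
  expect_lt(abs(mean(pair$arm1) - mean(pair$arm2)) /
              max(mean(pair$arm1), mean(pair$arm2)), 0.2)

  # a motionless 24 h recording dies in tail trimming
  prof <- subject_profile("still", "control", activity_level = 1e-9)
  rec <- simulate_subject(prof, sim_config(duration_h = 1, seed = 2))
  expect_error(preprocess_recording(rec), "empty after trimming")
})

test_that("sync recovery works through the full simulated chain", {
  # simulated bilateral recording with a known bracelet start offset
  cfg <- sim_config(duration_h = 1.5, seed = 11, start_offset_s = 15)
  rec <- simulate_subject(subject_profile("c", "control"), cfg)
  pair <- preprocess_recording(rec)
  expect_identical(pair$shift, as.integer(round(-15 * 2 / 3)))
})
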