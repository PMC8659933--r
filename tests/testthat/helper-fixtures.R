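# Shared fixtures and independent oracles for the test suite.

# -- constructors -----------------------------------------------------------

# Processed pair built directly (bypasses the raw simulator) for tests that
# only exercise downstream stages.
make_pair <- function(arm1, arm2, subject_id = "t1", label = "control",
                      rate_hz = 32 / 48, shift = 0L) {
  armasym:::new_processed_pair(arm1, arm2, rate_hz, shift, subject_id, label)
}

# Synthetic processed pair with lognormal activity; `asym` scales arm2.
random_pair <- function(subject_id, label, n = 4800, asym = 1, seed = 1) {
  set.seed(seed)
  base <- stats::rlnorm(n, meanlog = -2.5, sdlog = 0.8)
  noise <- function() stats::rlnorm(n, -5, 0.3)
  make_pair(base + noise(), asym * base + noise(),
            subject_id = subject_id, label = label)
}

# Cohort of synthetic processed pairs (fast; no raw-signal simulation).
synthetic_pair_cohort <- function(n_stroke, n_control, n = 4800, seed = 1) {
  pairs <- list()
  for (i in seq_len(n_stroke)) {
    asym <- stats::runif(1, 0.05, 0.5)  # attenuated arm
    flip <- stats::runif(1) < 0.5
    p <- random_pair(sprintf("S%02d", i), "stroke", n = n,
                     asym = asym, seed = seed * 1000 + i)
    if (flip) {
      tmp <- p$arm1; p$arm1 <- p$arm2; p$arm2 <- tmp
    }
    pairs[[length(pairs) + 1]] <- p
  }
  for (i in seq_len(n_control)) {
    pairs[[length(pairs) + 1]] <-
      random_pair(sprintf("C%02d", i), "control", n = n,
                  seed = seed * 2000 + i)
  }
  pairs
}

random_window_set <- function(n_windows, L = 20, seed = 1) {
  set.seed(seed)
  x <- array(stats::runif(n_windows * 2 * L, 0, 2), dim = c(n_windows, 2, L))
  armasym:::new_window_set(x, sprintf("w%03d", seq_len(n_windows)),
                           rep("control", n_windows),
                           numeric(n_windows), 32 / 48)
}

# Simulated raw cohort, built once per test run and reused across tests.
.fixture_env <- new.env()
small_sim_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(
      8, 8, sim_config(duration_h = 2, seed = 424242))
    .fixture_env$pairs <- lapply(.fixture_env$cohort, preprocess_recording)
  }
  list(cohort = .fixture_env$cohort, pairs = .fixture_env$pairs)
}

# -- oracles ----------------------------------------------------------------

# Brute-force moving-average + stride + normalisation oracle: direct
# convolution with an expanding-window warm-up.
sdn_oracle <- function(x, ma_len = 96, decim = 48, norm = 64) {
  n <- length(x)
  ma <- numeric(n)
  for (i in seq_len(n)) {
    ma[i] <- mean(x[max(1, i - ma_len + 1):i])
  }
  ma[seq(1, n, by = decim)] / norm
}

# Analytic magnitude response of the prewarped bilinear Butterworth
# high-pass of order `ord`, cutoff fc, sampling rate fs.
butter_hp_gain <- function(f, fc = 3, fs = 32, ord = 5) {
  Om <- tan(pi * f / fs) / tan(pi * fc / fs)
  Om^ord / sqrt(1 + Om^(2 * ord))
}

# Least-squares amplitude of a sinusoid of frequency f in series y.
fit_amplitude <- function(y, f, fs) {
  t <- (seq_along(y) - 1) / fs
  co <- stats::lm.fit(cbind(sin(2 * pi * f * t), cos(2 * pi * f * t)), y)$coefficients
  sqrt(sum(co^2))
}

# Exhaustive-search sync oracle: independent double loop over all lags.
sync_oracle <- function(a1, a2, max_lag) {
  n1 <- length(a1); n2 <- length(a2)
  best_s <- NA; best_d <- Inf
  for (s in -max_lag:max_lag) {
    if (s >= 0) {
      len <- min(n1, n2 - s)
      if (len < 1) next
      d <- mean(abs(a1[seq_len(len)] - a2[s + seq_len(len)]))
    } else {
      len <- min(n1 + s, n2)
      if (len < 1) next
      d <- mean(abs(a1[-s + seq_len(len)] - a2[seq_len(len)]))
    }
    if (d < best_d - 1e-15 ||
        (abs(d - best_d) <= 1e-15 && abs(s) < abs(best_s))) {
      best_d <- d; best_s <- s
    }
  }
  best_s
}

# Pairwise-concordance AUC oracle (ties count one half).
auc_concordance <- function(scores, labels) {
  pos <- scores[labels == "stroke" | labels == TRUE]
  neg <- scores[labels == "control" | labels == FALSE]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exact null distribution of the (tie-free) Friedman statistic for k
# treatments and N blocks by dynamic programming over per-block rank
# permutations: returns the exact p-value P(stat >= obs) under the null.
friedman_exact_p <- function(obs_stat, k, N) {
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == k), ,
                 drop = FALSE]
  # distribution over column rank-sum vectors, built block by block
  dist <- list()
  dist[[paste(rep(0, k), collapse = ",")]] <- 1
  for (b in seq_len(N)) {
    nxt <- list()
    for (key in names(dist)) {
      sums <- as.numeric(strsplit(key, ",")[[1]])
      for (pi in seq_len(nrow(perms))) {
        ns <- sums + perms[pi, ]
        nk <- paste(ns, collapse = ",")
        nxt[[nk]] <- (nxt[[nk]] %||% 0) + dist[[key]]
      }
    }
    dist <- nxt
  }
  total <- sum(unlist(dist))
  hit <- 0
  for (key in names(dist)) {
    sums <- as.numeric(strsplit(key, ",")[[1]])
    stat <- 12 / (N * k * (k + 1)) * sum(sums^2) - 3 * N * (k + 1)
    if (stat >= obs_stat - 1e-9) hit <- hit + dist[[key]]
  }
  hit / total
}

`%||%` <- function(a, b) if (is.null(a)) b else a
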