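# Evaluation: subject-level splits, four-fold grid-search cross-validation,
# ROC/AUC with operating points, and the Friedman + post-hoc Nemenyi
# comparison across model families with a critical-difference diagram.

#' Stratified subject-level split
#'
#' Partitions subjects into groups of about equal size with roughly the
#' cohort's class ratio in each group; all windows of a subject always land
#' in one group. One group is designated the held-out test set, the others
#' are the cross-validation training folds.
#'
#' @param labels Named character vector mapping subject id to
#'   `"stroke"`/`"control"`.
#' @param seed RNG seed; the same seed reproduces the same plan.
#' @param n_groups Number of groups (default 5, i.e. ~20% each).
#' @param test_group_index Which group is the test set.
#' @return An object of class `split_plan` with `groups` (list of subject-id
#'   vectors) and `test_group_index`.
#' @export
split_subjects <- function(labels, seed = 1L, n_groups = 5L,
                           test_group_index = n_groups) {
  stopifnot(!is.null(names(labels)))
  classes <- split(names(labels), as.character(labels))
  small <- vapply(classes, length, 0L) < n_groups
  if (any(small)) {
    stopf("need at least %d subjects per class", n_groups)
  }
  groups <- replicate(n_groups, character(0), simplify = FALSE)
  with_seed(seed, {
    at <- 0L
    for (cl in names(classes)) {
      ids <- sample(classes[[cl]])
      for (id in ids) {
        g <- (at %% n_groups) + 1L
        groups[[g]] <- c(groups[[g]], id)
        at <- at + 1L
      }
    }
  })
  structure(list(groups = groups, test_group_index = as.integer(test_group_index),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$groups, length, 0L)
  cat(sprintf("Subject split: %d groups of sizes %s (test group %d)\n",
              length(x$groups), paste(sizes, collapse = "/"),
              x$test_group_index))
  invisible(x)
}

# Stratified partition of the test subjects into n_parts parts, each with
# at least one subject of each class.
split_test_parts <- function(labels, n_parts, seed = 1L) {
  plan <- split_subjects(labels, seed = seed, n_groups = as.integer(n_parts))
  plan$groups
}

#' ROC curve and AUC from confidence scores
#'
#' Threshold sweep over the unique scores (prediction positive when score
#' is at or above the threshold); AUC by trapezoidal integration of the
#' curve, which equals the pairwise concordance probability with ties
#' counted one half.
#'
#' @param scores Numeric confidence scores, higher meaning more stroke-like.
#' @param labels Labels (`"stroke"` positive / `"control"`), or a logical
#'   vector with `TRUE` positive.
#' @return An object of class `eval_roc`: data frame `roc` with threshold,
#'   sensitivity, specificity and confusion counts, plus `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else
    as.character(labels) == POSITIVE_CLASS
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0 || N == 0) stopf("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- pos[o]
  last <- cumsum(rep(1, length(s)))[!duplicated(s, fromLast = TRUE)]
  # cumulative counts at each distinct threshold (pred positive: >= thr)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  thr <- s[!duplicated(s)]
  roc <- data.frame(
    threshold = c(Inf, thr),
    sensitivity = c(0, tp / P),
    specificity = c(1, 1 - fp / N),
    tp = c(0, tp), fp = c(0, fp))
  fpr <- 1 - roc$specificity
  tprv <- roc$sensitivity
  auc <- sum(diff(fpr) * (utils::head(tprv, -1) + utils::tail(tprv, -1)) / 2)
  structure(list(roc = roc, auc = auc, n_pos = P, n_neg = N),
            class = "eval_roc")
}

#' @export
print.eval_roc <- function(x, ...) {
  op <- operating_point(x)
  cat(sprintf("ROC over %d+/%d- instances: AUC %.4f; operating point sens %.3f spec %.3f F1 %.3f\n",
              x$n_pos, x$n_neg, x$auc, op$sensitivity, op$specificity, op$f1))
  invisible(x)
}

#' @export
plot.eval_roc <- function(x, ...) {
  graphics::plot(1 - x$roc$specificity, x$roc$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Operating point of a ROC curve
#'
#' The point minimising the Euclidean distance to the ideal corner
#' (sensitivity 1, specificity 1); ties are broken toward the lowest
#' threshold. F1 is computed from the confusion matrix at that threshold.
#'
#' @param res An `eval_roc` object.
#' @return List with `sensitivity`, `specificity`, `f1` and `threshold`.
#' @export
operating_point <- function(res) {
  stopifnot(inherits(res, "eval_roc"))
  r <- res$roc
  d2 <- (1 - r$sensitivity)^2 + (1 - r$specificity)^2
  cand <- which(abs(d2 - min(d2)) <= 1e-12)
  i <- cand[which.min(r$threshold[cand])]
  tp <- r$tp[i]
  fp <- r$fp[i]
  fn <- res$n_pos - tp
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(sensitivity = r$sensitivity[i], specificity = r$specificity[i],
       f1 = f1, threshold = r$threshold[i])
}

#' Friedman rank test over a model-by-dataset performance matrix
#'
#' Ranks the k models within each of the N datasets (average ranks on
#' ties, rank 1 the best) and tests the null hypothesis that all models
#' perform equally, using the chi-square form of the statistic with the
#' standard tie correction. The F-distribution refinement and a
#' within-dataset permutation p-value are available as options.
#'
#' @param perf Numeric matrix, k models (rows) x N datasets (columns);
#'   higher values mean better performance.
#' @param method `"chisq"` (default), `"f"` (Iman-Davenport refinement) or
#'   `"permutation"`.
#' @param n_perm Number of shuffles for the permutation method.
#' @param seed RNG seed for the permutation method.
#' @return List of class `friedman_test` with `statistic`, `p.value`,
#'   `avg_ranks` (rank 1 = best) and the rank matrix.
#' @export
friedman_test <- function(perf, method = c("chisq", "f", "permutation"),
                          n_perm = 1e5, seed = 1L) {
  method <- match.arg(method)
  perf <- as.matrix(perf)
  k <- nrow(perf)
  N <- ncol(perf)
  if (k < 3 || N < 2) stopf("need at least 3 models and 2 datasets")
  ranks <- apply(perf, 2, function(col) rank(-col))   # k x N, 1 = best
  stat <- friedman_stat(ranks)
  p <- switch(
    method,
    chisq = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
    f = {
      ff <- (N - 1) * stat / (N * (k - 1) - stat)
      stats::pf(ff, k - 1, (k - 1) * (N - 1), lower.tail = FALSE)
    },
    permutation = with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        rp <- apply(ranks, 2, function(col) col[sample.int(k)])
        if (friedman_stat(rp) >= stat - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    }))
  structure(list(statistic = stat, p.value = p, method = method,
                 avg_ranks = rowMeans(ranks), ranks = ranks, k = k, N = N),
            class = "friedman_test")
}

# Chi-square Friedman statistic with tie correction; 0 whenever the rank
# sums are perfectly balanced (all-identical columns give 0, not NaN).
friedman_stat <- function(ranks) {
  k <- nrow(ranks)
  N <- ncol(ranks)
  num <- 12 * sum((rowSums(ranks) - N * (k + 1) / 2)^2)
  if (num == 0) return(0)
  ties <- unlist(apply(ranks, 2, function(col) {
    tab <- table(col)
    tab[tab > 1]
  }))
  den <- N * k * (k + 1) -
    (if (length(ties)) sum(ties^3 - ties) else 0) / (k - 1)
  num / den
}

#' @export
print.friedman_test <- function(x, ...) {
  cat(sprintf("Friedman test (%s): chi-square %.4f on %d models x %d datasets, p = %.4g\n",
              x$method, x$statistic, x$k, x$N, x$p.value))
  cat("Average ranks (1 = best):\n")
  print(round(x$avg_ranks, 3))
  invisible(x)
}

# Critical values q_alpha for the Nemenyi test: studentized range
# quantiles at infinite degrees of freedom divided by sqrt(2).
NEMENYI_Q <- list(
  `0.05` = c(`2` = 1.960, `3` = 2.343, `4` = 2.569, `5` = 2.728,
             `6` = 2.850, `7` = 2.949, `8` = 3.031, `9` = 3.102,
             `10` = 3.164),
  `0.1` = c(`2` = 1.645, `3` = 2.052, `4` = 2.291, `5` = 2.459,
            `6` = 2.589, `7` = 2.693, `8` = 2.780, `9` = 2.855,
            `10` = 2.920))

#' Nemenyi critical difference
#'
#' Two models differ significantly when their average ranks over N
#' datasets differ by more than `CD = q_alpha sqrt(k (k + 1) / (6 N))`.
#'
#' @param k Number of models (2-10).
#' @param N Number of datasets.
#' @param alpha Significance level, 0.05 or 0.1.
#' @return The critical difference (numeric scalar).
#' @export
nemenyi_cd <- function(k, N, alpha = 0.05) {
  qs <- NEMENYI_Q[[as.character(alpha)]]
  if (is.null(qs)) stopf("alpha must be 0.05 or 0.1")
  q <- qs[as.character(k)]
  if (is.na(q)) stopf("k = %d outside the embedded table (2-10)", k)
  unname(q * sqrt(k * (k + 1) / (6 * N)))
}

#' Critical-difference diagram structure
#'
#' Orders the models by average rank and marks every maximal run of models
#' whose rank span is below the critical difference as one connected
#' (statistically indistinguishable) group.
#'
#' @param avg_ranks Named numeric vector of average ranks (1 = best).
#' @param cd Critical difference from [nemenyi_cd()].
#' @return An object of class `cd_diagram`: ordered model names and ranks,
#'   the CD, and the connected groups (index vectors into the ordering;
#'   singletons omitted).
#' @export
critical_difference_diagram <- function(avg_ranks, cd) {
  o <- order(avg_ranks)
  r <- avg_ranks[o]
  k <- length(r)
  groups <- list()
  for (i in seq_len(k)) {
    j <- max(which(r - r[i] < cd))
    if (j > i) {
      if (length(groups) == 0 ||
          !(i >= groups[[length(groups)]][1] &&
            j <= groups[[length(groups)]][length(groups[[length(groups)]])])) {
        groups[[length(groups) + 1]] <- i:j
      }
    }
  }
  structure(list(models = names(r), avg_ranks = unname(r), cd = cd,
                 groups = groups),
            class = "cd_diagram")
}

#' @export
print.cd_diagram <- function(x, ...) {
  cat(sprintf("Critical-difference diagram (CD = %.3f)\n", x$cd))
  for (i in seq_along(x$models)) {
    cat(sprintf("  %d. %s (avg rank %.3f)\n", i, x$models[i], x$avg_ranks[i]))
  }
  if (length(x$groups) == 0) {
    cat("  All pairwise rank differences exceed the CD.\n")
  } else {
    for (g in x$groups) {
      cat(sprintf("  indistinguishable: {%s}\n",
                  paste(x$models[g], collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
plot.cd_diagram <- function(x, ...) {
  k <- length(x$models)
  lo <- floor(min(x$avg_ranks))
  hi <- ceiling(max(x$avg_ranks))
  if (hi == lo) hi <- lo + 1
  graphics::plot(NULL, xlim = c(lo - 0.2, hi + 0.2), ylim = c(-k - 1, 2.4),
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Average ranks (CD = %.2f)", x$cd))
  graphics::axis(3, at = lo:hi, pos = 1)
  # CD ruler
  graphics::segments(lo, 2.0, lo + x$cd, 2.0, lwd = 2)
  graphics::text(lo + x$cd / 2, 2.3, "CD", cex = 0.8)
  for (i in seq_len(k)) {
    y <- -i
    graphics::segments(x$avg_ranks[i], 1, x$avg_ranks[i], y)
    graphics::segments(x$avg_ranks[i], y, lo - 0.2, y)
    graphics::text(lo - 0.2, y, x$models[i], pos = 2, xpd = NA)
  }
  for (gi in seq_along(x$groups)) {
    g <- x$groups[[gi]]
    yb <- 0.35 + 0.25 * (gi - 1)
    graphics::segments(x$avg_ranks[g[1]] - 0.03,
                       yb, x$avg_ranks[g[length(g)]] + 0.03, yb, lwd = 3)
  }
  invisible(x)
}

ws_subset <- function(ws, rows) {
  structure(list(x = ws$x[rows, , , drop = FALSE],
                 meta = ws$meta[rows, , drop = FALSE],
                 rate_hz = ws$rate_hz),
            class = "window_set")
}

#' Four-fold grid-search cross-validation
#'
#' For every hyperparameter configuration, trains four models, each
#' holding out one of the four training groups as validation, and scores
#' the configuration by its mean validation AUC. The four fold models of
#' the winning configuration are returned for ensembling.
#'
#' @param family Model family.
#' @param grid Data frame of configurations (one per row); see
#'   [default_grids()].
#' @param feats Feature data frame for all training windows (must carry
#'   `subject_id` and `label`).
#' @param train_groups List of four subject-id vectors.
#' @param windows `window_set` aligned row-for-row with `feats` (needed for
#'   the conv net family).
#' @param seed RNG seed; fold models get seeds derived from it.
#' @param deep_args Extra arguments passed to [train_deep()].
#' @return List with `best_params`, the four fold `models`, `best_mean_auc`
#'   and the full `cv_table`.
#' @export
grid_search_cv <- function(family, grid, feats, train_groups, windows = NULL,
                           seed = 1L, deep_args = list()) {
  if (is.null(grid) || nrow(grid) == 0) stopf("empty hyperparameter grid")
  if (length(train_groups) != 4) stopf("expected 4 training groups")
  if (family == "conv_net" && is.null(windows)) {
    stopf("the conv net needs the raw windows")
  }
  rows_of <- lapply(train_groups, function(ids) {
    which(feats$subject_id %in% ids)
  })
  cv_table <- grid
  cv_table$mean_auc <- NA_real_
  best <- NULL
  for (ci in seq_len(nrow(grid))) {
    params <- as.list(grid[ci, , drop = FALSE])
    aucs <- numeric(4)
    models <- vector("list", 4)
    for (f in 1:4) {
      val_rows <- rows_of[[f]]
      trn_rows <- setdiff(seq_len(nrow(feats)), val_rows)
      fseed <- derive_seed(seed, sprintf("cfg%d-fold%d", ci, f))
      if (family == "conv_net") {
        m <- do.call(train_deep, c(
          list(cfg = params, train_ws = ws_subset(windows, trn_rows),
               val_ws = ws_subset(windows, val_rows), seed = fseed),
          deep_args))
        sc <- confidence(m, ws_subset(windows, val_rows))
      } else {
        m <- fit_paresis(feats[trn_rows, , drop = FALSE], family = family,
                         params = params, seed = fseed)
        sc <- confidence(m, feats[val_rows, , drop = FALSE])
      }
      aucs[f] <- roc_auc(sc, feats$label[val_rows])$auc
      models[[f]] <- m
    }
    cv_table$mean_auc[ci] <- mean(aucs)
    if (is.null(best) || mean(aucs) > best$best_mean_auc + 1e-12) {
      best <- list(best_params = params, models = models,
                   best_mean_auc = mean(aucs), fold_aucs = aucs)
    }
  }
  c(best, list(cv_table = cv_table))
}

windows_for_length <- function(pairs, window_min) {
  wcfg <- window_config(window_min)
  sets <- lapply(pairs, function(p) {
    suppressWarnings(make_windows(p, wcfg))
  })
  ws <- bind_windows(sets)
  list(ws = ws, feats = extract_features(ws))
}

#' Run the full model-comparison experiment
#'
#' For every window length and model family: grid search with four-fold
#' cross-validation on the four training groups, ensemble of the four fold
#' models, evaluation on the held-out test group as a whole (ROC, AUC,
#' operating point) and on `n_parts` subject-level parts of the test group.
#' The per-part AUCs over all window lengths form the rank matrix for the
#' Friedman test and post-hoc Nemenyi critical-difference analysis.
#'
#' @param pairs List of `processed_pair` objects (one per subject).
#' @param families Model families to compare.
#' @param window_min Window lengths (minutes) to evaluate.
#' @param grids Named list of per-family hyperparameter grids.
#' @param n_parts Number of test parts for the statistical comparison.
#' @param alpha Significance level for the Nemenyi test.
#' @param seed RNG seed controlling splits and model fits.
#' @param deep_args Extra arguments for [train_deep()].
#' @return An object of class `paresis_experiment`: tidy results tables,
#'   the per-part AUC matrix, and the Friedman/Nemenyi summary.
#' @export
run_experiment <- function(pairs, families = c("svm", "knn", "rf"),
                           window_min = WINDOW_MIN_CHOICES,
                           grids = default_grids(), n_parts = 10L,
                           alpha = 0.05, seed = 1L, deep_args = list()) {
  labels <- vapply(pairs, `[[`, "", "label")
  names(labels) <- vapply(pairs, `[[`, "", "subject_id")
  plan <- split_subjects(labels, seed = derive_seed(seed, "split"))
  test_ids <- plan$groups[[plan$test_group_index]]
  train_groups <- plan$groups[-plan$test_group_index]
  parts <- split_test_parts(labels[test_ids], n_parts,
                            seed = derive_seed(seed, "parts"))

  overall <- list()
  part_rows <- list()
  cv_summaries <- list()
  for (L in window_min) {
    wf <- windows_for_length(pairs, L)
    trn_rows <- which(wf$feats$subject_id %in% unlist(train_groups))
    tst_rows <- which(wf$feats$subject_id %in% test_ids)
    feats_trn <- wf$feats[trn_rows, , drop = FALSE]
    ws_trn <- ws_subset(wf$ws, trn_rows)
    for (fam in families) {
      gs <- grid_search_cv(fam, grids[[fam]], feats_trn, train_groups,
                           windows = if (fam == "conv_net") ws_trn,
                           seed = derive_seed(seed, paste0(fam, "-", L)),
                           deep_args = deep_args)
      ens <- build_ensemble(gs$models)
      newdata <- if (fam == "conv_net") ws_subset(wf$ws, tst_rows) else
        wf$feats[tst_rows, , drop = FALSE]
      sc <- confidence(ens, newdata)
      er <- roc_auc(sc, wf$feats$label[tst_rows])
      op <- operating_point(er)
      overall[[length(overall) + 1]] <- data.frame(
        model = fam, window_min = L, auc = er$auc,
        sensitivity = op$sensitivity, specificity = op$specificity,
        f1 = op$f1, cv_mean_auc = gs$best_mean_auc,
        stringsAsFactors = FALSE)
      for (pi in seq_along(parts)) {
        in_part <- wf$feats$subject_id[tst_rows] %in% parts[[pi]]
        pa <- roc_auc(sc[in_part], wf$feats$label[tst_rows][in_part])$auc
        part_rows[[length(part_rows) + 1]] <- data.frame(
          model = fam, window_min = L, part = pi, auc = pa,
          stringsAsFactors = FALSE)
      }
      cv_summaries[[paste(fam, L, sep = "_")]] <-
        list(best_params = gs$best_params, cv_table = gs$cv_table)
    }
  }
  overall <- do.call(rbind, overall)
  part_df <- do.call(rbind, part_rows)

  auc_matrix <- NULL
  friedman <- NULL
  cd <- NULL
  diagram <- NULL
  evals <- unique(part_df[, c("window_min", "part")])
  if (length(families) >= 3 && nrow(evals) >= 2) {
    auc_matrix <- matrix(
      NA_real_, nrow = length(families), ncol = nrow(evals),
      dimnames = list(families, paste0("w", evals$window_min, "p",
                                       evals$part)))
    for (e in seq_len(nrow(evals))) {
      sel <- part_df$window_min == evals$window_min[e] &
        part_df$part == evals$part[e]
      auc_matrix[part_df$model[sel], e] <- part_df$auc[sel]
    }
    friedman <- friedman_test(auc_matrix)
    cd <- nemenyi_cd(length(families), ncol(auc_matrix), alpha)
    diagram <- critical_difference_diagram(friedman$avg_ranks, cd)
  }
  structure(
    list(overall = overall, parts = part_df, auc_matrix = auc_matrix,
         friedman = friedman, cd = cd, diagram = diagram,
         split = plan, test_parts = parts, cv = cv_summaries,
         families = families, window_min = window_min, alpha = alpha,
         seed = seed),
    class = "paresis_experiment")
}

#' @export
print.paresis_experiment <- function(x, ...) {
  cat(sprintf("Paresis detection experiment: %d families x %d window lengths\n",
              length(x$families), length(x$window_min)))
  cat("Held-out test performance:\n")
  print(x$overall, row.names = FALSE, digits = 3)
  if (!is.null(x$friedman)) {
    cat("\n")
    print(x$friedman)
    cat(sprintf("Nemenyi critical difference (alpha %.2f): %.3f\n",
                x$alpha, x$cd))
  }
  invisible(x)
}

#' @export
summary.paresis_experiment <- function(object, ...) {
  print(object)
  if (!is.null(object$diagram)) print(object$diagram)
  invisible(object)
}

#' @export
plot.paresis_experiment <- function(x, ...) {
  if (is.null(x$diagram)) {
    stopf("no critical-difference diagram (fewer than 3 families)")
  }
  plot(x$diagram, ...)
}
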