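test_that("subject splits are stratified partitions of about 20% each", {
  labels <- c(rep("stroke", 84), rep("control", 101))
  names(labels) <- sprintf("s%03d", 1:185)
  plan <- split_subjects(labels, seed = 5)
  sizes <- vapply(plan$groups, length, 0L)
  expect_true(all(sizes %in% 36:38))
  expect_setequal(unlist(plan$groups), names(labels))
  expect_equal(sum(sizes), 185L)
  # class ratio in each group close to the cohort ratio (84/185)
  for (g in plan$groups) {
    expect_lt(abs(mean(labels[g] == "stroke") - 84 / 185), 0.05)
  }
  # determinism / seed sensitivity
  expect_identical(split_subjects(labels, seed = 5), plan)
  expect_false(identical(split_subjects(labels, seed = 6)$groups,
                         plan$groups))
  few <- c(a = "stroke", b = "stroke", c = "control", d = "control")
  expect_error(split_subjects(few), "at least 5")
})

test_that("ROC/AUC match the worked example and the concordance oracle", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8),
               c("control", "control", "stroke", "stroke"))
  expect_equal(r$auc, 0.75)

  expect_equal(roc_auc(c(1, 2, 3, 10), c(F, F, T, T))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(T, T, F, F))$auc, 0.0)

  # sensitivity is non-decreasing as the threshold decreases
  set.seed(8)
  sc <- rnorm(50)
  lb <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  roc <- roc_auc(sc, lb)$roc
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$specificity) <= 0))

  # trapezoid equals brute-force pairwise concordance, ties included
  for (i in 1:200) {
    set.seed(i)
    n <- sample(5:40, 1)
    sc <- sample(round(runif(n), 2))  # duplicates force ties
    lb <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(roc_auc(sc, lb)$auc, auc_concordance(sc, lb),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("pROC agrees with the trapezoidal AUC", {
  skip_if_not_installed("pROC")
  set.seed(21)
  sc <- rnorm(60)
  lb <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  expect_equal(roc_auc(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("operating point minimises distance to the ideal corner", {
  perfect <- roc_auc(c(1, 2, 3, 10), c(F, F, T, T))
  op <- operating_point(perfect)
  expect_equal(c(op$sensitivity, op$specificity, op$f1), c(1, 1, 1))

  ex <- roc_auc(c(0.1, 0.4, 0.35, 0.8),
                c("control", "control", "stroke", "stroke"))
  op <- operating_point(ex)
  d2 <- (1 - ex$roc$sensitivity)^2 + (1 - ex$roc$specificity)^2
  expect_equal((1 - op$sensitivity)^2 + (1 - op$specificity)^2, min(d2))

  # exhaustive check on random instances
  for (i in 1:25) {
    set.seed(i)
    r <- roc_auc(rnorm(30), sample(c(TRUE, FALSE), 30, replace = TRUE))
    op <- operating_point(r)
    d2 <- (1 - r$roc$sensitivity)^2 + (1 - r$roc$specificity)^2
    expect_equal((1 - op$sensitivity)^2 + (1 - op$specificity)^2, min(d2))
  }

  # distance ties resolve to the lowest threshold
  tie <- roc_auc(c(1, 2), c(TRUE, FALSE))
  expect_equal(operating_point(tie)$threshold, 1)
})

test_that("Friedman statistic matches the closed form and stats::friedman.test", {
  # identical performance everywhere: statistic 0, p 1
  ft <- friedman_test(matrix(0.9, nrow = 3, ncol = 6))
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p.value, 1)

  # one model strictly dominant, fixed rank order on every dataset
  N <- 10
  M <- rbind(rep(0.9, N), rep(0.8, N), rep(0.7, N))
  ft <- friedman_test(M)
  rank_sums <- c(1, 2, 3) * N
  closed <- 12 / (N * 3 * 4) * sum(rank_sums^2) - 3 * N * 4
  expect_equal(ft$statistic, closed)
  expect_equal(ft$avg_ranks, c(1, 2, 3), ignore_attr = TRUE)

  # agreement with the base-R implementation on random tie-free matrices
  for (i in 1:20) {
    set.seed(i)
    M <- matrix(rnorm(4 * 7), nrow = 4)
    ours <- friedman_test(M)
    ref <- stats::friedman.test(t(M))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-12)
  }
  expect_error(friedman_test(matrix(1, 2, 5)), "at least 3")
})

test_that("rank matrix columns sum to k(k+1)/2 with tie-adjusted ranks", {
  set.seed(4)
  M <- matrix(sample(seq(0.5, 1, 0.05), 3 * 12, replace = TRUE), nrow = 3)
  ft <- friedman_test(M)
  expect_equal(unname(colSums(ft$ranks)), rep(6, 12))
})

test_that("permutation p-value matches the exact enumeration", {
  set.seed(17)
  M <- matrix(rnorm(3 * 8, sd = 0.7) + c(0.6, 0, -0.3), nrow = 3)
  ft <- friedman_test(M, method = "permutation", n_perm = 2e4, seed = 99)
  p_exact <- friedman_exact_p(friedman_test(M)$statistic, 3, 8)
  mc_sd <- sqrt(p_exact * (1 - p_exact) / 2e4)
  expect_lt(abs(ft$p.value - p_exact), 4 * mc_sd + 1e-4)
})

test_that("Nemenyi critical differences come from the studentized range", {
  for (alpha in c(0.05, 0.1)) {
    for (k in 2:10) {
      q_ref <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2)
      expect_equal(nemenyi_cd(k, 1, alpha), q_ref * sqrt(k * (k + 1) / 6),
                   tolerance = 2e-3)
    }
  }
  # k = 5, N = 60 worked value
  expect_equal(nemenyi_cd(5, 60), 2.728 * sqrt(30 / 360), tolerance = 1e-12)
  # monotone decreasing in N; quadrupling N halves the CD
  cds <- vapply(c(10, 20, 40, 80), function(N) nemenyi_cd(5, N), 0)
  expect_true(all(diff(cds) < 0))
  expect_equal(nemenyi_cd(5, 40), nemenyi_cd(5, 10) / 2)
  expect_error(nemenyi_cd(15, 10), "outside")
  expect_error(nemenyi_cd(5, 10, alpha = 0.2), "alpha")
})

test_that("critical-difference grouping follows the rank-span rule", {
  all_equal <- critical_difference_diagram(
    c(a = 2, b = 2, c = 2), cd = 0.5)
  expect_length(all_equal$groups, 1)
  expect_equal(all_equal$groups[[1]], 1:3)

  apart <- critical_difference_diagram(
    c(a = 1, b = 3, c = 5), cd = 0.5)
  expect_length(apart$groups, 0)

  mixed <- critical_difference_diagram(
    c(m1 = 1.0, m2 = 1.2, m3 = 3.0), cd = 0.5)
  expect_length(mixed$groups, 1)
  expect_equal(mixed$models[mixed$groups[[1]]], c("m1", "m2"))
})

test_that("grid search scores configurations by mean fold AUC", {
  pairs <- synthetic_pair_cohort(10, 10, n = 1300, seed = 6)
  wf <- armasym:::windows_for_length(pairs, 15)
  labels <- vapply(pairs, `[[`, "", "label")
  names(labels) <- vapply(pairs, `[[`, "", "subject_id")
  plan <- split_subjects(labels, seed = 2)
  train_groups <- plan$groups[1:4]
  trn <- wf$feats[wf$feats$subject_id %in% unlist(train_groups), ]

  single <- data.frame(k = 7)
  gs <- grid_search_cv("knn", single, trn, train_groups, seed = 3)
  expect_equal(gs$best_params$k, 7)
  expect_equal(gs$best_mean_auc, mean(gs$fold_aucs))
  expect_length(gs$models, 4)

  # a rank-destroying configuration (gamma so large that every point is
  # only similar to itself, flattening validation scores) never beats a
  # working one
  grid <- data.frame(C = c(10, 10), gamma = c(1e6, 0.1))
  gs2 <- grid_search_cv("svm", grid, trn, train_groups, seed = 3)
  expect_equal(gs2$best_params$gamma, 0.1)
  expect_equal(gs2$cv_table$mean_auc[2], gs2$best_mean_auc)
  expect_error(grid_search_cv("svm", data.frame(), trn, train_groups),
               "empty")
})

test_that("the experiment produces 10 parts x 6 window lengths = 60 evaluations", {
  pairs <- synthetic_pair_cohort(50, 50, n = 5040, seed = 9)
  grids <- list(svm = data.frame(C = 10, gamma = 0.1),
                knn = data.frame(k = 11),
                rf = data.frame(n_trees = 100, min_samples_split = 2,
                                criterion = "gini"))
  exp <- run_experiment(pairs, families = c("svm", "knn", "rf"),
                        window_min = c(15, 30, 45, 60, 90, 120),
                        grids = grids, n_parts = 10, seed = 31)
  for (fam in c("svm", "knn", "rf")) {
    expect_equal(sum(exp$parts$model == fam), 60L)
  }
  expect_equal(dim(exp$auc_matrix), c(3L, 60L))
  expect_false(anyNA(exp$auc_matrix))
  expect_s3_class(exp$friedman, "friedman_test")
  expect_equal(exp$cd, nemenyi_cd(3, 60, 0.05))

  # subject-level discipline: no test subject appears in a training group
  test_ids <- exp$split$groups[[exp$split$test_group_index]]
  expect_length(intersect(test_ids,
                          unlist(exp$split$groups[-exp$split$test_group_index])),
                0)
  # the 10 parts partition the test subjects
  expect_setequal(unlist(exp$test_parts), test_ids)
})

test_that("a cohort with no group effect rarely rejects the Friedman null", {
  grids <- list(svm = data.frame(C = 1, gamma = 0.1),
                knn = data.frame(k = 5),
                rf = data.frame(n_trees = 50, min_samples_split = 2,
                                criterion = "gini"))
  rejections <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    # symmetric pairs for everyone: the labels carry no signal
    pairs <- synthetic_pair_cohort(0, 32, n = 1300, seed = 100 + s)
    for (i in 1:16) pairs[[i]]$label <- "stroke"
    exp <- run_experiment(pairs, families = c("svm", "knn", "rf"),
                          window_min = c(15, 30), grids = grids,
                          n_parts = 2, seed = 200 + s)
    if (exp$friedman$p.value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})
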