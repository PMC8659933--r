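# Windows with controlled asymmetry: stroke windows have one quiet arm.
toy_windows <- function(n_per_class = 30, L = 60, seed = 1) {
  set.seed(seed)
  x <- array(0, dim = c(2 * n_per_class, 2, L))
  for (i in seq_len(n_per_class)) {
    x[i, 1, ] <- runif(L, 0.8, 1.2)          # stroke: active vs quiet
    x[i, 2, ] <- runif(L, 0, 0.05)
    x[n_per_class + i, 1, ] <- runif(L, 0.4, 0.6)  # control: balanced
    x[n_per_class + i, 2, ] <- runif(L, 0.4, 0.6)
  }
  armasym:::new_window_set(
    x, sprintf("t%03d", seq_len(2 * n_per_class)),
    rep(c("stroke", "control"), each = n_per_class),
    numeric(2 * n_per_class), 2 / 3)
}

# Feature frame with all columns zero except mean1; used to place training
# points at exact distances from the origin.
point_features <- function(mean1, label) {
  f <- as.data.frame(matrix(0, nrow = length(mean1),
                            ncol = length(armasym:::FEATURE_NAMES),
                            dimnames = list(NULL, armasym:::FEATURE_NAMES)))
  f$mean1 <- mean1
  f$label <- label
  f$subject_id <- sprintf("p%d", seq_along(mean1))
  f
}

test_that("all three classical families separate separable features", {
  ws <- toy_windows()
  feats <- extract_features(ws)
  for (fam in c("svm", "knn", "rf")) {
    m <- fit_paresis(feats, family = fam, seed = 3)
    auc <- roc_auc(confidence(m, feats), feats$label)$auc
    expect_equal(auc, 1.0, tolerance = 1e-12,
                 label = sprintf("training AUC for %s", fam))
  }
})

test_that("confidence scores have their family-specific meanings", {
  ws <- toy_windows()
  feats <- extract_features(ws)

  # rf: unanimous trees on a point deep inside the stroke cluster -> 1.0
  mrf <- fit_paresis(feats, family = "rf",
                     params = list(n_trees = 100), seed = 5)
  deep_stroke <- feats[1, , drop = FALSE]
  expect_equal(unname(confidence(mrf, deep_stroke)), 1.0)

  # knn, k = 3: exactly 2 stroke points among the 3 nearest -> 2/3
  train <- point_features(c(1, 2, 3, 50, 60),
                          c("stroke", "stroke", "control",
                            "control", "stroke"))
  mknn <- fit_paresis(train, family = "knn", params = list(k = 3),
                      augment = FALSE)
  expect_equal(unname(confidence(mknn, point_features(0, "control"))), 2 / 3)

  # svm: the sign of the decision value agrees with the binary prediction
  msvm <- fit_paresis(feats, family = "svm", seed = 5)
  sc <- confidence(msvm, feats)
  cls <- predict(msvm, feats, type = "class")
  expect_true(all((sc >= 0) == (cls == "stroke")))
})

test_that("single-class training data is rejected", {
  feats <- extract_features(toy_windows())
  ctrl <- feats[feats$label == "control", ]
  expect_error(fit_paresis(ctrl, family = "svm"), "both classes")
})

test_that("average pooling reduces windows blockwise", {
  expect_equal(avg_pool_input(matrix(c(1, 3, 5, 7), nrow = 1), 2),
               matrix(c(2, 6), nrow = 1))
  ws <- random_window_set(3, L = 600, seed = 4)
  pooled <- avg_pool_input(ws, 2)
  expect_equal(dim(pooled$x), c(3, 2, 300))
  expect_equal(pooled$x[1, 1, 1], mean(ws$x[1, 1, 1:2]))
  expect_identical(avg_pool_input(ws, 1), ws)
  expect_error(avg_pool_input(ws, 0), ">= 1")
  # trailing remainder dropped
  ws7 <- random_window_set(2, L = 7, seed = 5)
  expect_equal(dim(avg_pool_input(ws7, 2)$x)[3], 3L)
})

test_that("ensembles average member confidences", {
  # four knn members whose 5-nearest neighbourhoods of the origin hold
  # 1, 2, 3 and 4 stroke points -> member scores 0.2, 0.4, 0.6, 0.8
  members <- lapply(1:4, function(j) {
    lab <- c(rep("stroke", j), rep("control", 5 - j))
    fit_paresis(point_features(1:5, lab), family = "knn",
                params = list(k = 5), augment = FALSE)
  })
  ens <- build_ensemble(members)
  probe <- point_features(0, "control")
  expect_equal(vapply(members, function(m)
    unname(confidence(m, probe)), 0), c(0.2, 0.4, 0.6, 0.8))
  expect_equal(unname(confidence(ens, probe)), 0.5)

  # identical members: the ensemble score equals the member score
  same <- fit_paresis(point_features(1:5, c("stroke", "stroke", "control",
                                            "control", "control")),
                      family = "knn", params = list(k = 5), augment = FALSE)
  ens2 <- build_ensemble(list(same, same, same, same))
  expect_equal(confidence(ens2, probe), confidence(same, probe))

  expect_error(build_ensemble(members[1:3]), "exactly 4")
  feats <- extract_features(toy_windows())
  other <- fit_paresis(feats, family = "rf", seed = 1)
  expect_error(build_ensemble(c(members[1:3], list(other))), "one family")
})

test_that("a perfect-member ensemble keeps AUC 1 (svm rescaling included)", {
  feats <- extract_features(toy_windows())
  members <- lapply(1:4, function(j)
    fit_paresis(feats, family = "svm", params = list(C = 10, gamma = 0.1),
                seed = j))
  ens <- build_ensemble(members)
  sc <- confidence(ens, feats)
  expect_true(all(sc >= 0 & sc <= 1))  # min-max standardised members
  expect_equal(roc_auc(sc, feats$label)$auc, 1.0)
})

test_that("swap augmentation removes side bias in the scores", {
  fix <- small_sim_cohort()
  wf <- armasym:::windows_for_length(fix$pairs, 15)
  m <- fit_paresis(wf$feats, family = "svm", seed = 11)   # augmented
  auc_orig <- roc_auc(confidence(m, wf$feats), wf$feats$label)$auc
  auc_swap <- roc_auc(confidence(m, swap_features(wf$feats)),
                      wf$feats$label)$auc
  expect_lt(abs(auc_orig - auc_swap), 0.02)
})
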