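# Classifier stage: RBF-SVM, k-nearest-neighbours and random forest on the
# 14 asymmetry features, each exposing the confidence score its family
# admits (signed SVM decision value, fraction of positive neighbours,
# fraction of positive trees), plus the four-fold ensemble combiner.

POSITIVE_CLASS <- "stroke"
MODEL_FAMILIES <- c("svm", "knn", "rf", "conv_net")

as_label_factor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c("control", "stroke"))
  if (length(bad) > 0) stopf("unknown labels: %s", paste(bad, collapse = ", "))
  factor(y, levels = c("control", "stroke"))
}

feature_matrix <- function(x) {
  if (inherits(x, "window_set")) {
    x <- extract_features(x)
  }
  x <- as.data.frame(x)
  missing <- setdiff(FEATURE_NAMES, names(x))
  if (length(missing) > 0) {
    stopf("missing feature columns: %s", paste(missing, collapse = ", "))
  }
  as.matrix(x[, FEATURE_NAMES])
}

#' Default hyperparameter grids
#'
#' Grids spanning each family's operating range at desk scale: SVM cost and
#' kernel width, neighbour counts, forest size and split control, and the
#' convolutional net's initial learning rate and input pooling factor. The
#' random-forest split criterion is Gini impurity (see the methods
#' vignette).
#'
#' @return Named list of data frames, one per model family.
#' @export
default_grids <- function() {
  list(
    svm = expand.grid(C = c(0.1, 1, 10, 100), gamma = c(0.01, 0.1, 1)),
    knn = data.frame(k = c(3, 5, 11, 21)),
    rf = expand.grid(n_trees = c(100, 300), min_samples_split = c(2, 5, 10),
                     criterion = "gini", stringsAsFactors = FALSE),
    conv_net = expand.grid(initial_lr = c(1e-3, 1e-4),
                           downsample_factor = c(1, 2, 4, 8)))
}

#' Average-pool the time axis of a window set
#'
#' Each channel is averaged over consecutive blocks of `factor` samples; a
#' trailing remainder shorter than one block is dropped. Factor 2 reduces a
#' 2 x 600 window to 2 x 300.
#'
#' @param ws A `window_set` (or a 2 x L matrix for a single window).
#' @param factor Positive integer pooling factor; 1 is the identity.
#' @return The reduced window set (or matrix).
#' @export
avg_pool_input <- function(ws, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stopf("pooling factor must be >= 1")
  if (factor == 1) return(ws)
  pool_mat <- function(m) {
    nb <- ncol(m) %/% factor
    out <- matrix(0, nrow(m), nb)
    for (b in seq_len(nb)) {
      out[, b] <- rowMeans(m[, ((b - 1) * factor + 1):(b * factor),
                             drop = FALSE])
    }
    out
  }
  if (is.matrix(ws)) return(pool_mat(ws))
  stopifnot(inherits(ws, "window_set"))
  L <- dim(ws$x)[3]
  nb <- L %/% factor
  n <- dim(ws$x)[1]
  out <- array(0, dim = c(n, 2, nb))
  for (ch in 1:2) {
    m <- matrix(ws$x[, ch, seq_len(nb * factor)], nrow = n)
    # columns grouped in consecutive blocks of `factor`
    for (b in seq_len(nb)) {
      out[, ch, b] <- rowMeans(m[, ((b - 1) * factor + 1):(b * factor),
                                 drop = FALSE])
    }
  }
  ws$x <- out
  ws$rate_hz <- ws$rate_hz / factor
  ws
}

#' Fit a paresis classifier
#'
#' The single fitting entry point for all model families. Classical
#' families (`"svm"`, `"knn"`, `"rf"`) are fitted on the 14 asymmetry
#' features; by default the training set is augmented with its arm-swapped
#' copy so the model cannot learn a left/right preference. The
#' convolutional family is fitted from raw windows via [train_deep()].
#'
#' @param x Feature data frame (from [extract_features()]) or a
#'   `window_set`; for `family = "conv_net"` a `window_set` is required.
#' @param y Labels (`"stroke"` / `"control"`); defaults to the `label`
#'   column carried by `x`.
#' @param family One of `"svm"`, `"knn"`, `"rf"`, `"conv_net"`.
#' @param params Named list / one-row data frame of hyperparameters
#'   (SVM: `C`, `gamma`; KNN: `k`; RF: `n_trees`, `min_samples_split`,
#'   `criterion`; conv net: `initial_lr`, `downsample_factor`).
#' @param augment Add the arm-swapped copy of the training set
#'   (default `TRUE`).
#' @param seed RNG seed for stochastic fitters.
#' @param ... Passed on to [train_deep()] for the conv net family.
#' @return An object of class `paresis_model`.
#' @export
fit_paresis <- function(x, y = NULL, family = c("svm", "knn", "rf", "conv_net"),
                        params = list(), augment = TRUE, seed = 1L, ...) {
  family <- match.arg(family)
  params <- as.list(params)
  if (family == "conv_net") {
    stopf("fit the conv net with train_deep() (it needs a validation set)")
  }
  if (is.null(y)) {
    if (inherits(x, "window_set")) y <- x$meta$label
    else y <- x$label
  }
  y <- as_label_factor(y)
  feats <- if (inherits(x, "window_set")) extract_features(x) else
    as.data.frame(x)
  X <- feature_matrix(feats)
  if (nlevels(droplevels(y)) < 2) {
    stopf("training data must contain both classes")
  }
  if (augment) {
    X <- rbind(X, feature_matrix(swap_features(feats)))
    y <- factor(c(as.character(y), as.character(y)),
                levels = levels(y))
  }
  fit <- with_seed(seed, switch(
    family,
    svm = fit_svm(X, y, params),
    knn = list(train = X, y = y, k = as.integer(params$k %||% 5)),
    rf = fit_rf(X, y, params)))
  structure(list(family = family, fit = fit, params = params,
                 positive = POSITIVE_CLASS, seed = seed),
            class = "paresis_model")
}

fit_svm <- function(X, y, params) {
  m <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                  cost = params$C %||% 1, gamma = params$gamma %||% 0.1,
                  scale = TRUE)
  # e1071 orients decision values toward the first training label seen;
  # record the orientation so higher confidence always means stroke.
  dv <- attr(stats::predict(m, X, decision.values = TRUE), "decision.values")
  lv <- strsplit(colnames(dv)[1], "/")[[1]]
  list(model = m, orient = if (lv[1] == POSITIVE_CLASS) 1 else -1)
}

fit_rf <- function(X, y, params) {
  crit <- params$criterion %||% "gini"
  if (!identical(as.character(crit), "gini")) {
    stopf("the random-forest backend supports the gini criterion only")
  }
  mss <- as.integer(params$min_samples_split %||% 2)
  randomForest::randomForest(
    X, y, ntree = as.integer(params$n_trees %||% 300),
    nodesize = max(1L, as.integer(ceiling(mss / 2))))
}

#' Confidence score of a fitted model
#'
#' SVM: signed decision-function value (positive toward stroke);
#' KNN: fraction of the k nearest neighbours labelled stroke;
#' RF: fraction of trees voting stroke;
#' conv net: value of the positive (stroke) softmax output node.
#'
#' @param model A `paresis_model` or `paresis_ensemble`.
#' @param newdata Feature data frame or `window_set` as appropriate.
#' @param ... Unused.
#' @return Numeric score vector, higher meaning more stroke-like.
#' @export
confidence <- function(model, newdata, ...) UseMethod("confidence")

#' @export
confidence.paresis_model <- function(model, newdata, ...) {
  if (model$family == "conv_net") {
    return(convnet_confidence(model, newdata))
  }
  X <- feature_matrix(newdata)
  switch(
    model$family,
    svm = {
      dv <- attr(stats::predict(model$fit$model, X, decision.values = TRUE),
                 "decision.values")
      as.numeric(dv[, 1]) * model$fit$orient
    },
    knn = {
      pred <- class::knn(model$fit$train, X, model$fit$y, k = model$fit$k,
                         prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == POSITIVE_CLASS, p, 1 - p)
    },
    rf = {
      stats::predict(model$fit, X, type = "prob")[, POSITIVE_CLASS]
    })
}

#' @export
predict.paresis_model <- function(object, newdata,
                                  type = c("confidence", "class"), ...) {
  type <- match.arg(type)
  sc <- confidence(object, newdata)
  if (type == "confidence") return(sc)
  thr <- if (object$family == "svm") 0 else 0.5
  factor(ifelse(sc >= thr, POSITIVE_CLASS, "control"),
         levels = c("control", POSITIVE_CLASS))
}

#' @export
print.paresis_model <- function(x, ...) {
  ps <- paste(names(x$params), unlist(lapply(x$params, format)),
              sep = "=", collapse = ", ")
  cat(sprintf("Paresis classifier: %s (%s)\n", x$family,
              if (nzchar(ps)) ps else "default parameters"))
  invisible(x)
}

#' Combine the four cross-validation fold models into an ensemble
#'
#' @param members List of exactly four `paresis_model` objects of the same
#'   family, one per training fold.
#' @return An object of class `paresis_ensemble`.
#' @export
build_ensemble <- function(members) {
  if (length(members) != 4) stopf("an ensemble has exactly 4 members")
  fams <- unique(vapply(members, `[[`, "", "family"))
  if (length(fams) != 1) stopf("ensemble members must share one family")
  structure(list(members = members, family = fams), class = "paresis_ensemble")
}

#' Ensemble confidence score
#'
#' The arithmetic mean of the member confidences. SVM decision values are
#' unbounded margins, so each member's scores are min-max rescaled to
#' \[0, 1\] over the scored batch before averaging (rank-preserving per
#' member); the bounded scores of the other families are averaged as-is.
#'
#' @param model A `paresis_ensemble`.
#' @param newdata Feature data frame or `window_set`.
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
confidence.paresis_ensemble <- function(model, newdata, ...) {
  scores <- vapply(model$members, confidence,
                   numeric(row_count(newdata)), newdata = newdata)
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  if (model$family == "svm") {
    scores <- apply(scores, 2, function(s) {
      rng <- range(s)
      if (diff(rng) < 1e-300) rep(0.5, length(s))
      else (s - rng[1]) / diff(rng)
    })
    if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  }
  rowMeans(scores)
}

#' @export
predict.paresis_ensemble <- function(object, newdata,
                                     type = c("confidence", "class"), ...) {
  type <- match.arg(type)
  sc <- confidence(object, newdata)
  if (type == "confidence") return(sc)
  factor(ifelse(sc >= 0.5, POSITIVE_CLASS, "control"),
         levels = c("control", POSITIVE_CLASS))
}

#' @export
print.paresis_ensemble <- function(x, ...) {
  cat(sprintf("Four-fold ensemble of %s classifiers\n", x$family))
  invisible(x)
}

row_count <- function(x) {
  if (inherits(x, "window_set")) dim(x$x)[1] else nrow(as.data.frame(x))
}
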