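#' Classification metrics from a confusion matrix
#'
#' HS (the minority group) is the positive class: sensitivity is the HS
#' detection rate, specificity the LS detection rate. Percentages are
#' additionally reported truncated (not rounded) to two decimals, the
#' convention used in the performance tables this package mirrors
#' (e.g. 41/43 -> 95.34).
#'
#' @param tp,fn,tn,fp non-negative confusion counts (`tp + fn` = number of
#'   HS subjects, `tn + fp` = number of LS subjects).
#' @return list with proportions `accuracy`, `sensitivity`, `specificity`,
#'   `f1`, and truncated two-decimal percentages `accuracy_pct`,
#'   `sensitivity_pct`, `specificity_pct` plus `f1_2dp`. Metrics with zero
#'   denominators are `NaN` and flagged in `undefined`.
#' @export
metrics_from_confusion <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  acc <- (tp + tn) / (tp + fn + tn + fp)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NaN
  undefined <- c(sensitivity = is.nan(sens), specificity = is.nan(spec),
                 f1 = is.nan(f1))
  list(accuracy = acc, sensitivity = sens, specificity = spec, f1 = f1,
       accuracy_pct = truncate_pct(acc),
       sensitivity_pct = if (is.nan(sens)) NaN else truncate_pct(sens),
       specificity_pct = if (is.nan(spec)) NaN else truncate_pct(spec),
       f1_2dp = if (is.nan(f1)) NaN else truncate_2dp(f1),
       undefined = undefined)
}

#' Assemble the per-mood graph-feature table
#'
#' One row per subject; columns named `{metric}.{channel|GLOBAL}.{band}.{freq}`
#' for the per-channel metrics (`cc`, `strength`) and the whole-brain `ge`,
#' over every band and Ganzfeld target frequency present. With the full
#' design (64 channels, 6 bands, 8 frequencies) this yields
#' 64 x 96 + 48 = 6192 columns. Missing (subject, band, frequency) cells
#' are an error.
#'
#' @param entries list of records, each a list with `subject`, `group`,
#'   `mood`, `target_frequency`, `band`, and `metrics` (a [graph_metrics()]
#'   object at the feature density).
#' @param mood the mood condition to assemble.
#' @return list with `x` (numeric subjects x features matrix), `y`
#'   (character group labels), `subjects`.
#' @export
assemble_features <- function(entries, mood) {
  entries <- Filter(function(e) e$mood == mood, entries)
  if (!length(entries)) stop("no entries for mood '", mood, "'")
  subjects <- sort(unique(vapply(entries, `[[`, "", "subject")))
  bands <- sort(unique(vapply(entries, `[[`, "", "band")))
  freqs <- sort(unique(vapply(entries, function(e)
    as.numeric(e$target_frequency), numeric(1))))
  channels <- names(entries[[1]]$metrics$strength)
  if (is.null(channels))
    channels <- as.character(seq_along(entries[[1]]$metrics$strength))
  key <- function(s, b, f) paste(s, b, f, sep = "|")
  idx <- stats::setNames(seq_along(entries), vapply(entries, function(e)
    key(e$subject, e$band, e$target_frequency), ""))
  missing <- character(0)
  cols_per_cell <- c(paste0("cc.", channels), paste0("strength.", channels),
                     "ge.GLOBAL")
  feat_names <- unlist(lapply(bands, function(b) lapply(freqs, function(f)
    paste0(cols_per_cell, ".", b, ".", f))))
  x <- matrix(NA_real_, length(subjects), length(feat_names),
              dimnames = list(subjects, feat_names))
  y <- stats::setNames(rep(NA_character_, length(subjects)), subjects)
  for (s in subjects) {
    for (b in bands) for (f in freqs) {
      i <- idx[key(s, b, f)]
      if (is.na(i)) { missing <- c(missing, key(s, b, f)); next }
      e <- entries[[i]]
      y[s] <- e$group
      x[s, paste0("cc.", channels, ".", b, ".", f)] <- e$metrics$cc[channels]
      x[s, paste0("strength.", channels, ".", b, ".", f)] <-
        e$metrics$strength[channels]
      x[s, paste0("ge.GLOBAL.", b, ".", f)] <- e$metrics$ge
    }
  }
  if (length(missing))
    stop("missing (subject|band|frequency) cells: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ...")
  list(x = x, y = unname(y), subjects = subjects)
}

#' Rank features by Welch t magnitude
#'
#' Computes the Welch t statistic of every feature column between the two
#' classes of the training rows and orders features by `|t|` descending;
#' ties (e.g. duplicated columns) keep their original column order.
#' Constant-in-both-classes columns get `t = 0`.
#'
#' @param x numeric matrix, rows = training subjects.
#' @param y class labels (two classes present).
#' @return character vector of feature names in rank order, with the `t`
#'   values as the `"t"` attribute.
#' @export
rank_features_welch <- function(x, y) {
  cl <- unique(y)
  if (length(cl) != 2) stop("training set must contain exactly two classes")
  a <- x[y == cl[1], , drop = FALSE]
  b <- x[y == cl[2], , drop = FALSE]
  tvals <- vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(a[, j]) == 0 && stats::sd(b[, j]) == 0) return(0)
    welch_t(a[, j], b[, j])$t
  }, numeric(1))
  ord <- order(-abs(tvals))   # stable: preserves column order on ties
  out <- colnames(x)[ord]
  attr(out, "t") <- tvals[ord]
  out
}

# ---- classifiers ----------------------------------------------------------

zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
zscore_apply <- function(x, zs) sweep(sweep(x, 2, zs$mu), 2, zs$sd, "/")

#' Fit a classifier
#'
#' Supported: `"dt"` (CART, Gini, unlimited depth), `"knn"` (K = 5,
#' Euclidean, training-fold z-scoring), `"lda"` (pooled covariance, with a
#' shrinkage fallback when singular), `"svm"` (linear kernel, unit cost,
#' training-fold z-scoring), `"rusboost"` (see [rusboost()]).
#'
#' @param name classifier name.
#' @param x training feature matrix.
#' @param y training labels (character; `"HS"` is the positive class).
#' @param params named list of classifier parameters.
#' @param seed integer seed (used by rusboost undersampling).
#' @return an object of class `ganznet_classifier`.
#' @export
fit_classifier <- function(name, x, y,
                           params = list(), seed = 1L) {
  y <- as.character(y)
  model <- switch(
    name,
    dt = {
      df <- data.frame(.y = factor(y), x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 2, cp = 0,
                                                  xval = 0))
    },
    knn = {
      zs <- zscore_fit(x)
      list(train = zscore_apply(x, zs), y = factor(y), zs = zs,
           k = params$k %||% 5)
    },
    lda = fit_lda_shrink(x, y),
    svm = {
      zs <- zscore_fit(x)
      list(fit = e1071::svm(zscore_apply(x, zs), factor(y),
                            kernel = "linear",
                            cost = params$cost %||% 1, scale = FALSE),
           zs = zs)
    },
    rusboost = rusboost(x, y,
                        n_rounds = params$n_rounds %||% 100,
                        maxdepth = params$maxdepth %||% 3,
                        learn_rate = params$learn_rate %||% 0.1,
                        undersample = params$undersample %||% TRUE,
                        seed = seed),
    stop("unknown classifier: '", name, "'"))
  structure(list(name = name, model = model), class = "ganznet_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_lda_shrink <- function(x, y) {
  fit <- tryCatch(suppressWarnings(MASS::lda(x, grouping = factor(y))),
                  error = function(e) NULL)
  if (!is.null(fit)) return(list(kind = "mass", fit = fit))
  # shrinkage fallback: pooled covariance blended toward its diagonal mean
  yl <- factor(y); lev <- levels(yl)
  mus <- lapply(lev, function(l) colMeans(x[yl == l, , drop = FALSE]))
  Sp <- Reduce(`+`, lapply(lev, function(l) {
    xs <- x[yl == l, , drop = FALSE]
    crossprod(sweep(xs, 2, colMeans(xs))) })) / (nrow(x) - length(lev))
  gamma <- 0.1
  Ss <- (1 - gamma) * Sp + gamma * mean(diag(Sp)) * diag(ncol(x))
  Si <- solve(Ss)
  priors <- as.numeric(table(yl)) / length(yl)
  list(kind = "shrink", mus = mus, Si = Si, lev = lev,
       log_priors = log(priors))
}

#' Predict with a fitted classifier
#' @param object a `ganznet_classifier`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.ganznet_classifier <- function(object, newdata, ...) {
  m <- object$model
  switch(
    object$name,
    dt = as.character(predict(m, data.frame(newdata, check.names = FALSE),
                              type = "class")),
    knn = as.character(class::knn(m$train, zscore_apply(newdata, m$zs),
                                  m$y, k = m$k)),
    lda = if (m$kind == "mass")
      as.character(predict(m$fit, newdata)$class)
    else {
      sc <- vapply(seq_along(m$lev), function(g) {
        d <- sweep(newdata, 2, m$mus[[g]])
        -0.5 * rowSums((d %*% m$Si) * d) + m$log_priors[g]
      }, numeric(nrow(newdata)))
      sc <- matrix(sc, nrow = nrow(newdata))
      m$lev[max.col(sc)]
    },
    svm = as.character(predict(m$fit, zscore_apply(newdata, m$zs))),
    rusboost = predict_rusboost(m, newdata))
}

#' RUSBoost: boosting with random undersampling
#'
#' AdaBoost.M1 where each round's training sample is balanced by randomly
#' undersampling the majority class down to the minority count, drawing
#' without replacement with probabilities proportional to the current
#' AdaBoost sample weights. The weak learner is a depth-limited CART tree.
#' Weighted error and the weight update follow the AdaBoost.M1 schedule
#' (correctly classified weights multiplied by `beta^learn_rate`,
#' `beta = err/(1-err)`); prediction is the `log(1/beta)`-weighted vote.
#' A first-round weak learner no better than chance stops training early
#' with a warning.
#'
#' @param x training feature matrix.
#' @param y training labels (two classes; minority count >= 2).
#' @param n_rounds boosting rounds (default 100).
#' @param maxdepth weak-learner tree depth (default 3).
#' @param learn_rate shrinkage on the boosting schedule (default 0.1).
#' @param undersample set `FALSE` to disable RUS (plain AdaBoost.M1).
#' @param seed integer seed for the undersampling draws.
#' @return an object of class `rusboost` with per-round trees, weights and
#'   sampled indices.
#' @export
rusboost <- function(x, y, n_rounds = 100, maxdepth = 3,
                     learn_rate = 0.1, undersample = TRUE, seed = 1L) {
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("rusboost needs exactly two classes")
  counts <- table(factor(y, lev))
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(lev, minority)
  if (min(counts) < 2) stop("minority class needs >= 2 samples")
  n <- nrow(x)
  w <- rep(1 / n, n)
  set.seed(derive_seed(seed, "rusboost"))
  rounds <- list()
  for (t in seq_len(n_rounds)) {
    if (undersample && counts[[minority]] < counts[[majority]]) {
      maj_idx <- which(y == majority)
      pw <- w[maj_idx]
      if (sum(pw) == 0) pw <- rep(1, length(maj_idx))
      sel_maj <- sample(maj_idx, counts[[minority]], prob = pw)
      idx <- c(which(y == minority), sel_maj)
    } else {
      idx <- seq_len(n)
    }
    df <- data.frame(.y = factor(y[idx], lev),
                     x[idx, , drop = FALSE], check.names = FALSE)
    tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                         weights = w[idx] / sum(w[idx]),
                         control = rpart::rpart.control(
                           minsplit = 2, cp = 0, xval = 0,
                           maxdepth = maxdepth))
    pred <- as.character(predict(tree, data.frame(x, check.names = FALSE),
                                 type = "class"))
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5) {
      if (t == 1) {
        warning("weak learner no better than chance on round 1; stopping")
        rounds[[t]] <- list(tree = tree, alpha = 0, idx = idx)
      }
      break
    }
    err <- max(err, 1e-10)
    beta <- err / (1 - err)
    alpha <- learn_rate * log(1 / beta)
    rounds[[t]] <- list(tree = tree, alpha = alpha, idx = idx)
    w[!miss] <- w[!miss] * beta^learn_rate
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  structure(list(rounds = rounds, levels = lev, learn_rate = learn_rate),
            class = "rusboost")
}

predict_rusboost <- function(m, newdata) {
  votes <- matrix(0, nrow(newdata), length(m$levels),
                  dimnames = list(NULL, m$levels))
  for (r in m$rounds) {
    if (r$alpha <= 0) next
    p <- as.character(predict(r$tree,
                              data.frame(newdata, check.names = FALSE),
                              type = "class"))
    votes[cbind(seq_len(nrow(newdata)), match(p, m$levels))] <-
      votes[cbind(seq_len(nrow(newdata)), match(p, m$levels))] + r$alpha
  }
  if (all(votes == 0)) votes[, 1] <- 1   # degenerate: no informative round
  m$levels[max.col(votes, ties.method = "first")]
}

#' Leave-one-out cross-validated classification
#'
#' One fold per subject. Feature ranking ([rank_features_welch()]) is
#' refit inside every training fold (no leakage) unless
#' `global_selection = TRUE`; the top `k` features are used. The aggregate
#' confusion over held-out predictions is summarized with HS as the
#' positive class.
#'
#' @param features a feature table from [assemble_features()] (list with
#'   `x`, `y`) or a plain matrix plus `y`.
#' @param classifier classifier name, see [fit_classifier()].
#' @param k number of top-ranked features to use (default 10).
#' @param y labels when `features` is a matrix.
#' @param params classifier parameters.
#' @param seed integer seed.
#' @param positive positive class label (default `"HS"`).
#' @param global_selection rank once on all subjects instead of per fold
#'   (leaks the held-out subject; for comparison only).
#' @return an object of class `classification_result`: per-fold
#'   predictions, confusion counts, and [metrics_from_confusion()] output.
#' @export
loo_cv <- function(features, classifier = "rusboost", k = 10, y = NULL,
                   params = list(), seed = 1L, positive = "HS",
                   global_selection = FALSE) {
  if (is.list(features) && !is.null(features$x)) {
    x <- features$x; y <- features$y
  } else x <- features
  stopifnot(is.matrix(x), length(y) == nrow(x), nrow(x) >= 3)
  y <- as.character(y)
  if (min(table(y)) < 3)
    stop("leave-one-out with per-fold feature ranking needs at least 3 ",
         "subjects in each class")
  k <- min(k, ncol(x))
  global_rank <- if (global_selection) rank_features_welch(x, y) else NULL
  preds <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    xt <- x[-i, , drop = FALSE]; yt <- y[-i]
    rk <- if (global_selection) global_rank else rank_features_welch(xt, yt)
    sel <- rk[seq_len(k)]
    fit <- fit_classifier(classifier, xt[, sel, drop = FALSE], yt,
                          params = params, seed = derive_seed(seed, i))
    preds[i] <- predict(fit, x[i, sel, drop = FALSE])
  }
  tp <- sum(preds == positive & y == positive)
  fn <- sum(preds != positive & y == positive)
  tn <- sum(preds != positive & y != positive)
  fp <- sum(preds == positive & y != positive)
  structure(list(classifier = classifier, k = k,
                 predicted = preds, truth = y,
                 confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
                 metrics = metrics_from_confusion(tp, fn, tn, fp)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  m <- x$metrics
  cat("<classification_result> ", x$classifier, " (k = ", x$k, ")\n",
      sep = "")
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  F1 %.2f\n",
              m$accuracy_pct, m$sensitivity_pct, m$specificity_pct, m$f1))
  cat("  confusion: TP=", x$confusion["TP"], " FN=", x$confusion["FN"],
      " TN=", x$confusion["TN"], " FP=", x$confusion["FP"], "\n", sep = "")
  invisible(x)
}
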