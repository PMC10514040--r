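test_that("confusion metrics reproduce the reported percentage arithmetic", {
  # 13/14 HS and 28/29 LS correct
  m <- metrics_from_confusion(tp = 13, fn = 1, tn = 28, fp = 1)
  expect_equal(m$accuracy_pct, 95.34)
  expect_equal(m$sensitivity_pct, 92.85)
  expect_equal(m$specificity_pct, 96.55)
  expect_equal(m$f1, 13 / 14, tolerance = 1e-12)
  expect_equal(m$f1_2dp, 0.92)
  # 12/14 and 25/29 correct
  m2 <- metrics_from_confusion(tp = 12, fn = 2, tn = 25, fp = 4)
  expect_equal(m2$accuracy_pct, 86.04)
  expect_equal(m2$sensitivity_pct, 85.71)
  expect_equal(m2$specificity_pct, 86.20)
  # perfect classification
  m3 <- metrics_from_confusion(14, 0, 29, 0)
  expect_equal(c(m3$accuracy_pct, m3$sensitivity_pct, m3$specificity_pct),
               c(100, 100, 100))
  expect_equal(m3$f1, 1)
  # undefined metrics are flagged, not silently zeroed
  m4 <- metrics_from_confusion(0, 0, 5, 2)
  expect_true(m4$undefined["sensitivity"])
})

test_that("feature assembly yields the documented column grid", {
  channels <- paste0("Ch", 1:5)
  entries <- list()
  for (s in c("S1", "S2", "S3")) for (b in c("delta", "theta"))
    for (f in c(10, 20))
      entries[[length(entries) + 1]] <-
        fake_entry(s, if (s == "S1") "HS" else "LS", "anxiety", f, b,
                   channels, base = length(entries) + 1)
  ft <- assemble_features(entries, "anxiety")
  # (2 metrics x 5 channels + 1 GE) x 2 bands x 2 freqs
  expect_equal(dim(ft$x), c(3, (2 * 5 + 1) * 2 * 2))
  expect_false(anyNA(ft$x))
  expect_true("cc.Ch1.delta.10" %in% colnames(ft$x))
  expect_true("ge.GLOBAL.theta.20" %in% colnames(ft$x))
  # per-channel feature count for one metric with the full 6 x 8 grid
  expect_equal(6 * 8, 48)
  # missing cells are an error naming the offender
  expect_error(assemble_features(entries[-1], "anxiety"), "missing")
  expect_error(assemble_features(entries, "serenity"), "no entries")
})

test_that("Welch-t feature ranking finds signal and respects ties", {
  set.seed(20)
  n <- 24
  y <- rep(c("HS", "LS"), each = n / 2)
  x <- matrix(rnorm(n * 10), n,
              dimnames = list(NULL, paste0("noise", 1:10)))
  x <- cbind(x, signal = ifelse(y == "HS", 5, 0) + rnorm(n, 0, 0.1))
  rk <- rank_features_welch(x, y)
  expect_equal(rk[1], "signal")
  # duplicated columns rank adjacently in stable column order
  x2 <- cbind(a = x[, "signal"], b = x[, "signal"], x[, 1:3])
  rk2 <- rank_features_welch(x2, y)
  expect_equal(rk2[1:2], c("a", "b"))
  # matches a direct per-column recomputation
  tor <- vapply(colnames(x), function(cn)
    oracle_welch_t(x[y == "HS", cn], x[y == "LS", cn])$t, numeric(1))
  expect_equal(unname(attr(rk, "t")), unname(tor[rk]), tolerance = 1e-10)
  expect_error(rank_features_welch(x, rep("HS", n)), "two classes")
})

test_that("all five classifiers reach 100% on separable clusters", {
  set.seed(30)
  n <- 20
  y <- rep(c("HS", "LS"), c(8, 12))
  x <- matrix(rnorm(n * 12), n,
              dimnames = list(NULL, paste0("f", 1:12)))
  x[y == "HS", 1:3] <- x[y == "HS", 1:3] + 8
  for (clf in c("dt", "knn", "lda", "svm", "rusboost")) {
    res <- loo_cv(x, classifier = clf, k = 5, y = y, seed = 1,
                  params = if (clf == "rusboost") list(n_rounds = 25)
                  else list())
    expect_equal(res$metrics$accuracy, 1,
                 info = paste("classifier", clf))
  }
  expect_error(loo_cv(x, classifier = "mlp", k = 5, y = y),
               "unknown classifier")
})

test_that("confusion counts partition the cohort", {
  set.seed(31)
  y <- rep(c("HS", "LS"), c(5, 9))
  x <- matrix(rnorm(14 * 6), 14, dimnames = list(NULL, paste0("f", 1:6)))
  res <- loo_cv(x, classifier = "dt", k = 3, y = y, seed = 2)
  expect_equal(unname(res$confusion["TP"] + res$confusion["FN"]), 5)
  expect_equal(unname(res$confusion["TN"] + res$confusion["FP"]), 9)
  m <- res$metrics
  expect_equal(m$accuracy,
               unname(res$confusion["TP"] + res$confusion["TN"]) / 14)
})

test_that("rusboost balances every round and learns separable data", {
  set.seed(32)
  y <- rep(c("HS", "LS"), c(6, 18))
  x <- matrix(rnorm(24 * 5), 24, dimnames = list(NULL, paste0("f", 1:5)))
  x[y == "HS", 1] <- x[y == "HS", 1] + 6
  fit <- rusboost(x, y, n_rounds = 20, seed = 3)
  for (r in fit$rounds) {
    cls <- table(y[r$idx])
    expect_equal(unname(cls["HS"]), unname(cls["LS"]))
    expect_equal(length(r$idx), 12)
  }
  pred <- predict(structure(list(name = "rusboost", model = fit),
                            class = "ganznet_classifier"), x)
  expect_equal(mean(pred == y), 1)
})

test_that("without undersampling rusboost equals plain AdaBoost.M1", {
  set.seed(33)
  y <- rep(c("HS", "LS"), each = 10)   # balanced
  x <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("f", 1:4)))
  x[y == "HS", 2] <- x[y == "HS", 2] + 1.5
  fit <- rusboost(x, y, n_rounds = 15, maxdepth = 2, learn_rate = 0.1,
                  undersample = FALSE, seed = 5)
  ref <- oracle_adaboost(x, y, n_rounds = 15, maxdepth = 2,
                         learn_rate = 0.1)
  set.seed(34)
  xt <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("f", 1:4)))
  got <- predict(structure(list(name = "rusboost", model = fit),
                           class = "ganznet_classifier"), xt)
  expect_equal(got, oracle_adaboost_predict(ref, xt))
})

test_that("held-out subjects cannot influence training-fold ranking", {
  set.seed(36)
  y <- rep(c("HS", "LS"), c(6, 8))
  x <- matrix(rnorm(14 * 9), 14, dimnames = list(NULL, paste0("f", 1:9)))
  i <- 3
  rk1 <- rank_features_welch(x[-i, ], y[-i])
  x2 <- x
  x2[i, ] <- 1e6   # corrupt the held-out subject only
  rk2 <- rank_features_welch(x2[-i, ], y[-i])
  expect_identical(as.character(rk1), as.character(rk2))
  # and the full LOO predictions for other folds are unaffected through
  # the training path
  expect_error(loo_cv(x[c(1, 2, 7, 8), ], classifier = "dt",
                      y = y[c(1, 2, 7, 8)]),
               "at least 3")
})
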