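# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written as plain loops / direct formulas,
# not via the code paths they validate.

# direct O(N^2) DFT analytic signal (no stats::fft): z = x + i * HT(x)
oracle_analytic_dft <- function(x) {
  N <- length(x)
  k <- 0:(N - 1)
  X <- vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * k / N)), complex(1))
  h <- numeric(N)
  if (N %% 2 == 0) {
    h[c(1, N / 2 + 1)] <- 1
    h[2:(N / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((N + 1) / 2)] <- 2
  }
  vapply(k, function(nn)
    sum(X * h * exp(2i * pi * k * nn / N)) / N, complex(1))
}

# Floyd-Warshall all-pairs shortest paths on lengths 1/w (0 = no edge)
oracle_global_efficiency <- function(W, normalize = TRUE) {
  N <- nrow(W)
  if (max(W) == 0) return(0)
  if (normalize) W <- W / max(W)
  D <- matrix(Inf, N, N)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in seq_len(N)) for (i in seq_len(N)) for (j in seq_len(N))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (N * (N - 1))
}

# per-node Onnela clustering by explicit (j, h) triangle enumeration
oracle_weighted_clustering <- function(W) {
  N <- nrow(W)
  Wn <- W / max(W)
  cc <- numeric(N)
  for (i in seq_len(N)) {
    t_i <- 0
    for (j in seq_len(N)) for (h in seq_len(N))
      t_i <- t_i + (Wn[i, j] * Wn[j, h] * Wn[i, h])^(1 / 3)
    t_i <- t_i / 2
    k_i <- sum(W[i, ] > 0)
    cc[i] <- if (k_i >= 2) 2 * t_i / (k_i * (k_i - 1)) else 0
  }
  cc
}

oracle_strength <- function(W) {
  vapply(seq_len(nrow(W)), function(i) {
    s <- 0
    for (j in seq_len(ncol(W))) s <- s + W[i, j]
    s
  }, numeric(1))
}

# textbook Welch t
oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

# BH step-up: sort, compare p_(i) to i*q/m, take the largest passing rank
oracle_fdr_mask <- function(p, q) {
  m <- length(p)
  o <- order(p)
  passing <- which(p[o] <= seq_len(m) * q / m)
  mask <- rep(FALSE, m)
  if (length(passing)) mask[o[seq_len(max(passing))]] <- TRUE
  mask
}

# plain AdaBoost.M1 with rpart weak learners, mirroring the documented
# schedule (correct weights multiplied by beta^learn_rate)
oracle_adaboost <- function(x, y, n_rounds, maxdepth, learn_rate) {
  y <- as.character(y)
  lev <- sort(unique(y))
  n <- nrow(x)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    df <- data.frame(.y = factor(y, lev), x, check.names = FALSE)
    tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                         weights = w / sum(w),
                         control = rpart::rpart.control(
                           minsplit = 2, cp = 0, xval = 0,
                           maxdepth = maxdepth))
    pred <- as.character(predict(tree, data.frame(x, check.names = FALSE),
                                 type = "class"))
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    beta <- err / (1 - err)
    trees[[length(trees) + 1]] <- tree
    alphas <- c(alphas, learn_rate * log(1 / beta))
    w[!miss] <- w[!miss] * beta^learn_rate
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(trees = trees, alphas = alphas, lev = lev)
}

oracle_adaboost_predict <- function(m, x) {
  votes <- matrix(0, nrow(x), length(m$lev))
  for (i in seq_along(m$trees)) {
    p <- as.character(predict(m$trees[[i]],
                              data.frame(x, check.names = FALSE),
                              type = "class"))
    votes[cbind(seq_len(nrow(x)), match(p, m$lev))] <-
      votes[cbind(seq_len(nrow(x)), match(p, m$lev))] + m$alphas[i]
  }
  m$lev[max.col(votes, ties.method = "first")]
}

# random symmetric non-negative weight matrix with zero diagonal
random_weight_matrix <- function(n, seed, sparsity = 0) {
  set.seed(seed)
  W <- matrix(runif(n * n), n, n)
  if (sparsity > 0) W[matrix(runif(n * n) < sparsity, n, n)] <- 0
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  W
}

# two-channel montage/plan for pairwise coupling checks
pair_plan <- function(kappa, band = "alpha_low") {
  m <- montage_spec(c("a", "b"))
  K <- matrix(c(0, kappa, kappa, 0), 2)
  coupling_plan(m, kappa = K, bands = band, subject_sd = 0)
}

# epoch-averaged pair PLV at the generator's phase level
pair_plv <- function(kappa, n_epochs, seed, band = "alpha_low") {
  plan <- pair_plan(kappa, band)
  rec <- generate_subject(plan, fs = 256, n_epochs = n_epochs,
                          epoch_len = 4, group = NA, seed = seed,
                          bands = eeg_bands(band),
                          subject_multiplier = 1, return_phases = TRUE)
  epoch_averaged_plv(rec, band, source = "phases")$values[1, 2]
}

# fabricated graph_metrics record for feature-assembly tests
fake_entry <- function(subject, group, mood, freq, band, channels,
                       base = 1) {
  gm <- structure(list(density = 0.08,
                       strength = stats::setNames(
                         base + seq_along(channels) / 10, channels),
                       cc = stats::setNames(
                         base / 2 + seq_along(channels) / 20, channels),
                       ge = base / 3, n_edges = 10L),
                  class = "graph_metrics")
  list(subject = subject, group = group, mood = mood,
       target_frequency = freq, band = band, metrics = gm)
}

expect_all_equal <- function(x, y, tol = 1e-10) {
  expect_lt(max(abs(x - y)), tol)
}
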