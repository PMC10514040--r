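#' Welch's two-sample t-test
#'
#' Unequal-variance t with Welch–Satterthwaite degrees of freedom and a
#' two-sided p-value. The sign convention throughout the package is
#' `a - b`; calling with `(HS, LS)` makes negative t mean "LS higher".
#' If both samples are constant with equal means, `t = 0, p = 1` by
#' convention; constant samples with unequal means are an error.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t`, `p`, `df`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    stop("degenerate samples: zero variance in both groups, unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' One-way two-group ANOVA F from summary statistics
#'
#' Computes the pooled-variance F statistic (equal to the square of the
#' pooled two-sample t) from per-group mean, SD and n, with
#' `df = (1, n1 + n2 - 2)`. Useful for demographics tables where only
#' summaries are printed.
#'
#' @param g1,g2 lists (or named vectors) with `mean`, `sd`, `n`.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_f_from_summary <- function(g1, g2) {
  g1 <- as.list(g1); g2 <- as.list(g2)
  n1 <- g1$n; n2 <- g2$n
  stopifnot(g1$sd >= 0, g2$sd >= 0, n1 >= 2, n2 >= 2)
  if (n1 + n2 <= 3) stop("need n1 + n2 > 3")
  sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / (n1 + n2 - 2)
  Fv <- (n1 * n2 / (n1 + n2)) * (g1$mean - g2$mean)^2 / sp2
  df2 <- n1 + n2 - 2
  list(F = Fv, df1 = 1, df2 = df2,
       p = stats::pf(Fv, 1, df2, lower.tail = FALSE))
}

#' Pearson chi-square for a 2x2 table
#'
#' No continuity correction, 1 degree of freedom.
#'
#' @param tab 2x2 matrix of counts.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), sum(tab) > 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a zero marginal makes the chi-square undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' Standardizes the sample by its own mean and SD and tests against the
#' standard normal CDF. Because the parameters are estimated from the same
#' sample, the test is conservative (used as a screen, not a gate).
#'
#' @param x numeric sample, n >= 4, nonzero variance.
#' @return list with `statistic`, `p`.
#' @export
ks_normality <- function(x) {
  stopifnot(length(x) >= 4)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance: normality test undefined")
  z <- (x - mean(x)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values and the significance mask at level `q`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `q_values` and logical `significant` (`q_value < q`).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(q_values = numeric(0),
                                  significant = logical(0)))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  qv <- stats::p.adjust(pvals, method = "BH")
  list(q_values = qv, significant = qv < q)
}

#' Two-group comparisons of network quantities
#'
#' Edge-, node-, or global-level Welch t comparisons between the HS and LS
#' groups, with the package's fixed sign convention HS - LS (negative t
#' means LS higher). Edge-level p-values are FDR-corrected across edges
#' within the family defined by one (band x mood x target frequency) cell;
#' node-level (per-channel strength/CC at the feature density) and
#' global-level (GE per density) comparisons report raw p-values with a
#' `significant` flag at `p_threshold`, plus q-values for optional FDR use.
#'
#' @param values_hs,values_ls numeric matrices: subjects x features
#'   (features = edges, channels, or density levels; column names label
#'   them).
#' @param level one of `"edge"`, `"node_metric"`, `"global"`.
#' @param fdr_q FDR level for the edge family (default 0.05).
#' @param p_threshold raw significance threshold for node/global levels.
#' @return data.frame with one row per feature: `feature`, per-group means,
#'   `t`, `df`, `p`, `q`, `significant`, `direction` (sign of t).
#' @export
compare_networks <- function(values_hs, values_ls,
                             level = c("edge", "node_metric", "global"),
                             fdr_q = 0.05, p_threshold = 0.05) {
  level <- match.arg(level)
  stopifnot(is.matrix(values_hs), is.matrix(values_ls),
            ncol(values_hs) == ncol(values_ls),
            nrow(values_hs) >= 2, nrow(values_ls) >= 2)
  feats <- colnames(values_hs)
  if (is.null(feats)) feats <- as.character(seq_len(ncol(values_hs)))
  res <- lapply(seq_len(ncol(values_hs)), function(j) {
    a <- values_hs[, j]; b <- values_ls[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
      return(c(t = 0, df = NA_real_, p = 1))
    w <- welch_t(a, b)
    c(t = w$t, df = w$df, p = w$p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(feature = feats,
                    mean_hs = colMeans(values_hs),
                    mean_ls = colMeans(values_ls),
                    t = res[, "t"], df = res[, "df"], p = res[, "p"],
                    stringsAsFactors = FALSE, row.names = NULL)
  fb <- fdr_bh(out$p, fdr_q)
  out$q <- fb$q_values
  out$significant <- if (level == "edge") fb$significant else
    out$p < p_threshold
  out$direction <- sign(out$t)
  out
}
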