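#' Proportional (density) thresholding of a weighted network
#'
#' Ranks the upper-triangle weights in descending order and retains the top
#' `round(density * N(N-1)/2)` edges (round half away from zero), zeroing
#' the rest; retained weights are preserved, never rescaled. Ties at the
#' cut are broken by stable `(i, j)` index order.
#'
#' @param W symmetric non-negative matrix with zero diagonal (e.g. pruned
#'   PLV values).
#' @param density fraction of possible edges to retain, in `(0, 1]`.
#' @return an object of class `weighted_graph`: list with `W` (thresholded
#'   matrix), `density` (requested), `density_actual` (retained fraction of
#'   possible edges), `n_edges`, `N`.
#' @export
threshold_proportional <- function(W, density) {
  if (inherits(W, "plv_matrix")) W <- W$values
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  if (any(W < 0)) stop("weights must be non-negative")
  if (any(diag(W) != 0)) stop("diagonal must be zero")
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  N <- nrow(W)
  n_possible <- N * (N - 1) / 2
  keep_n <- round_half_up(density * n_possible)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  nonzero <- sum(w > 0)
  if (keep_n > nonzero) {
    warning("requested ", keep_n, " edges but only ", nonzero,
            " nonzero weights survive; keeping all nonzero")
    keep_n <- nonzero
  }
  Wt <- matrix(0, N, N, dimnames = dimnames(W))
  if (keep_n > 0) {
    ord <- order(-w, ut[, 1], ut[, 2])   # stable (i, j) tie-break
    sel <- ord[seq_len(keep_n)]
    Wt[ut[sel, , drop = FALSE]] <- w[sel]
    Wt <- Wt + t(Wt)
  }
  structure(list(W = Wt, density = density,
                 density_actual = keep_n / n_possible,
                 n_edges = as.integer(keep_n), N = N),
            class = "weighted_graph")
}

as_weighted_graph <- function(g) {
  if (inherits(g, "weighted_graph")) return(g)
  stopifnot(is.matrix(g))
  structure(list(W = g, density = NA_real_,
                 density_actual = mean(g[upper.tri(g)] > 0),
                 n_edges = sum(g[upper.tri(g)] > 0), N = nrow(g)),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("<weighted_graph> ", x$N, " nodes, ", x$n_edges,
      " edges (density ", signif(x$density_actual, 3), ")\n", sep = "")
  invisible(x)
}

#' Node strength (weighted degree)
#'
#' Sum of the link weights incident to each node.
#'
#' @param g a `weighted_graph` or plain symmetric weight matrix.
#' @return named numeric vector, one value per node.
#' @export
node_strength <- function(g) {
  g <- as_weighted_graph(g)
  rowSums(g$W)
}

#' Onnela weighted clustering coefficient
#'
#' Per-node geometric-mean triangle intensity
#' `t_i = 1/2 * sum_{j,h} (w_ij w_jh w_ih)^(1/3)` normalized by the number
#' of possible triangles `k_i (k_i - 1) / 2`, with weights first divided by
#' the matrix maximum so that values lie in `[0, 1]`. Nodes with degree
#' below 2 get 0.
#'
#' @param g a `weighted_graph` or plain symmetric weight matrix.
#' @return named numeric vector of per-node clustering coefficients.
#' @export
weighted_clustering <- function(g) {
  g <- as_weighted_graph(g)
  W <- g$W
  mx <- max(W)
  if (mx == 0) return(stats::setNames(numeric(g$N), rownames(W)))
  Wn <- (W / mx)^(1 / 3)
  t_i <- diag(Wn %*% Wn %*% Wn) / 2
  k <- rowSums(W > 0)
  cc <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  stats::setNames(cc, rownames(W))
}

#' Weighted global efficiency
#'
#' Mean inverse shortest weighted path length over all ordered node pairs,
#' `GE = 1/(N(N-1)) * sum_{i != j} 1/d(i,j)`. Edge lengths are the inverse
#' of the (max-normalized, by default) weights; shortest paths by Dijkstra.
#' Unreachable pairs contribute zero. With max-normalization, `GE` lies in
#' `[0, 1]`.
#'
#' @param g a `weighted_graph` or plain symmetric weight matrix.
#' @param normalize divide weights by the matrix maximum before inverting
#'   to lengths (default `TRUE`), making GE scale-invariant.
#' @return scalar efficiency.
#' @export
global_efficiency <- function(g, normalize = TRUE) {
  g <- as_weighted_graph(g)
  W <- g$W
  N <- g$N
  if (max(W) == 0) return(0)
  if (normalize) W <- W / max(W)
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(ig)$weight
  D <- igraph::distances(ig, weights = len, algorithm = "dijkstra")
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (N * (N - 1))
}

#' All graph metrics at one density
#'
#' @param W symmetric weight matrix (pruned PLV values) or `plv_matrix`.
#' @param density proportional threshold level.
#' @return an object of class `graph_metrics`: list with `density`,
#'   `strength` and `cc` (per-node vectors), `ge` (scalar), `n_edges`.
#' @export
graph_metrics <- function(W, density) {
  g <- threshold_proportional(W, density)
  structure(list(density = density,
                 strength = node_strength(g),
                 cc = weighted_clustering(g),
                 ge = global_efficiency(g),
                 n_edges = g$n_edges),
            class = "graph_metrics")
}

#' Graph metrics over a proportional density sweep
#'
#' Computes [graph_metrics()] at each density of a grid (default 0.01 to
#' 0.50 in steps of 0.01). The entry at `feature_density` (default 0.08) is
#' flagged as the feature source for classification. Densities for which
#' too few nonzero edges survive are recorded as missing with a warning.
#'
#' @param W symmetric weight matrix or `plv_matrix`.
#' @param densities density grid in `(0, 1]`.
#' @param feature_density the density whose metrics feed feature
#'   extraction.
#' @return list with `per_density` (list of `graph_metrics`, `NULL` where
#'   unattainable), `densities`, `feature_density`, and `feature_metrics`
#'   (the `graph_metrics` at `feature_density`).
#' @export
metrics_over_density_sweep <- function(W, densities = seq(0.01, 0.50, 0.01),
                                       feature_density = 0.08) {
  stopifnot(all(densities > 0 & densities <= 1))
  if (inherits(W, "plv_matrix")) W <- W$values
  N <- nrow(W)
  n_possible <- N * (N - 1) / 2
  nonzero <- sum(W[upper.tri(W)] > 0)
  per <- stats::setNames(vector("list", length(densities)),
                         format(densities))
  missing <- character(0)
  for (i in seq_along(densities)) {
    d <- densities[i]
    if (round_half_up(d * n_possible) > nonzero) {
      missing <- c(missing, format(d))
      next
    }
    per[[i]] <- graph_metrics(W, d)
  }
  if (length(missing))
    warning("densities unattainable (too few surviving edges): ",
            paste(missing, collapse = ", "))
  fi <- which(abs(densities - feature_density) < 1e-9)
  list(per_density = per, densities = densities,
       feature_density = feature_density,
       feature_metrics = if (length(fi)) per[[fi[1]]] else NULL)
}
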