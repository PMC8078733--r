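# Shared-nearest-neighbour graph + modularity community detection over the
# smoothed signature expression, with a data-driven resolution choice.

knn_indices <- function(x, k) {
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))  # deterministic tie-break by index
    ord[ord != i][seq_len(k)]
  }, integer(k)))
}

# SNN graph: Jaccard weights over kNN adjacency (self included in each
# neighbourhood, as is conventional) via sparse matrix products
snn_graph <- function(x, k = 20, prune = 1 / 15) {
  nn <- knn_indices(x, k)
  n <- nrow(nn)
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1),
    j = as.vector(t(cbind(seq_len(n), nn))),
    x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(adj)           # |N_i intersect N_j|
  sz <- k + 1
  tri <- Matrix::triu(inter, 1)
  idx <- Matrix::which(tri > 0, arr.ind = TRUE)
  inter_v <- tri[idx]
  jac <- inter_v / (2 * sz - inter_v)
  keep <- jac >= prune
  list(i = idx[keep, 1], j = idx[keep, 2], w = jac[keep], n = n)
}

#' Cluster cells on smoothed signature expression
#'
#' Builds a shared-nearest-neighbour (SNN) graph with Jaccard edge weights
#' over the k-nearest-neighbour sets and partitions it with Louvain
#' modularity optimization at the given resolution. The result is
#' deterministic for a fixed seed. Clustering quality is recorded as the
#' mean pairwise Pearson correlation of signature expression vectors within
#' clusters (pooled over all within-cluster pairs).
#'
#' @param x cells x genes numeric matrix (smoothed scaled signature
#'   expression).
#' @param resolution positive modularity resolution; larger values give more
#'   clusters.
#' @param k neighbour count for the SNN graph (default 20).
#' @param seed integer seed for the community detection.
#' @param prune Jaccard threshold below which SNN edges are dropped.
#' @return An object of class `cluster_assignment`: list with `cluster`
#'   (integer per cell, labels 1..n_clusters), `n_clusters`, `resolution`,
#'   `quality`, `k`, `seed`.
#' @export
cluster_cells <- function(x, resolution = 1, k = 20, seed = 1,
                          prune = 1 / 15) {
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 cells to cluster", call. = FALSE)
  k <- min(k, n - 1)
  g <- snn_graph(x, k = k, prune = prune)
  graph <- igraph::graph_from_edgelist(cbind(g$i, g$j), directed = FALSE)
  graph <- igraph::add_vertices(graph, max(0, n - igraph::vcount(graph)))
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(graph, weights = g$w,
                                  resolution = resolution)
  cl <- as.integer(igraph::membership(comm))
  # relabel contiguously by first appearance
  cl <- as.integer(factor(cl, levels = unique(cl)))
  names(cl) <- rownames(x)
  structure(
    list(cluster = cl, n_clusters = max(cl), resolution = resolution,
         quality = cluster_quality(x, cl), k = k, seed = seed),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "cluster_assignment: %d cells in %d clusters (resolution %g, quality %.3f)\n",
    length(x$cluster), x$n_clusters, x$resolution, x$quality))
  invisible(x)
}

# mean within-cluster pairwise Pearson correlation of cell signature vectors,
# pooled over pairs; cells with zero variance across genes are excluded
cluster_quality <- function(x, cluster) {
  g <- ncol(x)
  if (g < 2) return(NA_real_)
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (g - 1))
  ok <- sdv > 0
  if (!any(ok)) return(NA_real_)
  z <- (x[ok, , drop = FALSE] - mu[ok]) / sdv[ok]
  cl <- cluster[ok]
  tot <- 0; npairs <- 0
  for (c0 in unique(cl)) {
    zc <- z[cl == c0, , drop = FALSE]
    nc <- nrow(zc)
    if (nc < 2) next
    s <- colSums(zc)
    tot <- tot + (sum(s^2) - sum(zc^2)) / 2
    npairs <- npairs + nc * (nc - 1) / 2
  }
  if (npairs == 0) return(NA_real_)
  tot / (npairs * (g - 1))
}

#' Choose a clustering resolution from a grid
#'
#' Clusters at every resolution in the grid and applies the selection rule:
#' the smallest resolution whose within-cluster expression-consistency
#' quality (see [cluster_cells]) reaches `quality_floor`; if none does, the
#' quality-maximizing resolution. The full grid log is returned so the
#' choice is auditable.
#'
#' @param x cells x genes matrix (smoothed scaled signature expression).
#' @param resolutions non-empty numeric grid of candidate resolutions.
#' @param k neighbour count for the SNN graph.
#' @param seed integer seed.
#' @param quality_floor consistency floor for the early-stop rule
#'   (default 0.9); `NULL` always takes the quality maximizer.
#' @return A list with `resolution` (chosen value), `assignment` (the
#'   [cluster_cells] result at that resolution), `rule` (which rule fired)
#'   and `log` (data frame resolution / n_clusters / quality).
#' @export
select_resolution <- function(x, resolutions = c(0.25, 0.5, 1, 2),
                              k = 20, seed = 1, quality_floor = 0.9) {
  resolutions <- sort(as.numeric(resolutions))
  if (length(resolutions) == 0) stop("resolution grid is empty", call. = FALSE)
  fits <- lapply(resolutions, function(r)
    cluster_cells(x, resolution = r, k = k, seed = seed))
  qual <- vapply(fits, function(f) f$quality, numeric(1))
  log <- data.frame(resolution = resolutions,
                    n_clusters = vapply(fits, function(f) f$n_clusters,
                                        integer(1)),
                    quality = qual)
  pick <- NA_integer_; rule <- "max-quality"
  if (!is.null(quality_floor)) {
    hit <- which(!is.na(qual) & qual >= quality_floor)
    if (length(hit) > 0) {
      pick <- hit[1]
      rule <- "smallest-resolution-above-floor"
    }
  }
  if (is.na(pick)) {
    q2 <- ifelse(is.na(qual), -Inf, qual)
    pick <- which.max(q2)
  }
  list(resolution = resolutions[pick], assignment = fits[[pick]],
       rule = rule, log = log)
}
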