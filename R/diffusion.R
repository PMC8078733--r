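#' Build a kNN-kernel affinity matrix between cells
#'
#' For each cell, Euclidean distances to its `k` nearest neighbours are
#' passed through an adaptive decay kernel `exp(-(d / sigma_i)^decay)` with
#' `sigma_i` the distance to the cell's k-th neighbour. The diagonal is set
#' to 1 and the matrix symmetrized as `(A + t(A)) / 2`, so the neighbourhood
#' support is symmetric. Duplicate cells (zero distance) borrow `sigma_i`
#' from the first strictly positive neighbour distance; a cell with no
#' positive distance to any other cell is an error.
#'
#' @param x cells x genes numeric matrix (scaled signature expression).
#' @param k neighbour count (must be < number of cells).
#' @param decay kernel decay exponent (alpha).
#' @return A symmetric non-negative cells x cells affinity matrix with
#'   entries in \[0, 1\].
#' @export
build_affinity <- function(x, k = 15, decay = 2) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  a <- matrix(0, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) {
    di <- d[i, ]
    ord <- order(di)
    ord <- ord[ord != i]
    nn <- ord[seq_len(k)]
    sigma <- di[nn[k]]
    if (sigma == 0) {
      pos <- di[di > 0]
      if (length(pos) == 0L)
        stop("cell ", i, " has zero distance to every other cell",
             call. = FALSE)
      sigma <- min(pos)
    }
    a[i, nn] <- exp(-(di[nn] / sigma)^decay)
    a[i, i] <- 1
  }
  (a + t(a)) / 2
}

#' Row-normalize an affinity matrix into a Markov transition matrix
#'
#' @param affinity non-negative square matrix with no all-zero row.
#' @return Row-stochastic matrix of the same dimensions.
#' @export
markov_normalize <- function(affinity) {
  affinity <- as.matrix(affinity)
  if (any(affinity < 0)) stop("affinity must be non-negative", call. = FALSE)
  rs <- rowSums(affinity)
  if (any(rs == 0))
    stop("isolated cell: affinity matrix has an all-zero row", call. = FALSE)
  affinity / rs
}

#' Construct a diffusion operator over cells
#'
#' Combines [build_affinity] and [markov_normalize] into the Markov
#' diffusion operator used for MAGIC-style expression smoothing: a
#' row-stochastic cell-cell transition matrix plus a diffusion time `t`.
#'
#' @param x cells x genes scaled matrix the operator is built on.
#' @param k neighbour count (default 15).
#' @param decay kernel decay exponent (default 2).
#' @param t non-negative integer diffusion time (default 3).
#' @return An object of class `diffusion_operator` with elements
#'   `transition`, `t`, `k`, `decay`.
#' @export
diffusion_operator <- function(x, k = 15, decay = 2, t = 3) {
  if (t < 0) stop("diffusion time t must be non-negative", call. = FALSE)
  structure(
    list(transition = markov_normalize(build_affinity(x, k = k,
                                                      decay = decay)),
         t = as.integer(t), k = k, decay = decay),
    class = "diffusion_operator"
  )
}

#' @export
print.diffusion_operator <- function(x, ...) {
  cat(sprintf("diffusion_operator: %d cells, k = %d, decay = %g, t = %d\n",
              nrow(x$transition), x$k, x$decay, x$t))
  invisible(x)
}

#' Smooth expression with a diffusion operator
#'
#' Computes `transition^t %*% x` by `t` successive multiplications:
#' each cell's expression is replaced by a weighted average over its graph
#' neighbourhood, diffused `t` steps. `t = 0` returns the input unchanged.
#'
#' @param x cells x genes matrix, rows matching the operator's cells.
#' @param op a [diffusion_operator].
#' @param t diffusion time; defaults to the operator's `t`.
#' @return Smoothed matrix of the same dimensions.
#' @export
smooth_expression <- function(x, op, t = op$t) {
  stopifnot(inherits(op, "diffusion_operator"))
  x <- as.matrix(x)
  if (nrow(x) != nrow(op$transition))
    stop("operator was built on a different number of cells", call. = FALSE)
  if (t < 0) stop("diffusion time t must be non-negative", call. = FALSE)
  out <- x
  for (s in seq_len(t)) out <- op$transition %*% out
  dimnames(out) <- dimnames(x)
  out
}
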