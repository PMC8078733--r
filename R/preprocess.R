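#' QC thresholds for cell filtering
#'
#' Cells are kept when the number of detected genes lies in
#' `[min_genes, max_genes]` (inclusive) and the mitochondrial count fraction
#' is at most `max_mito_fraction`; cells with strictly more than the
#' mitochondrial cutoff are removed.
#'
#' @param min_genes minimum detected genes per cell (default 200).
#' @param max_genes maximum detected genes per cell (default 5000, within
#'   the conventional 4000-7000 range for whole-tissue 10x data).
#' @param max_mito_fraction maximum mitochondrial count fraction
#'   (default 0.10).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 5000,
                          max_mito_fraction = 0.10) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes",
                                   call. = FALSE)
  if (max_mito_fraction <= 0 || max_mito_fraction >= 1)
    stop("max_mito_fraction must be in (0, 1)", call. = FALSE)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Removes cells with too few or too many detected genes and cells whose
#' mitochondrial count fraction exceeds the threshold (strictly greater
#' than; a cell at exactly the cutoff is retained). The gene set is never
#' changed. Applying the filter twice gives the same result as applying it
#' once.
#'
#' @param x an [emt_counts] object with mito flags (possibly all `FALSE`).
#' @param thresholds a [qc_thresholds] object.
#' @return A list with `counts` (filtered [emt_counts]) and `report`
#'   (removed counts per criterion and cells retained).
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "emt_counts"))
  thr <- thresholds
  detected <- rowSums(x$counts > 0)
  total <- rowSums(x$counts)
  mito_total <- if (any(x$mito))
    rowSums(x$counts[, x$mito, drop = FALSE]) else rep(0, nrow(x$counts))
  mito_frac <- ifelse(total > 0, mito_total / total, 0)
  low <- detected < thr$min_genes
  high <- detected > thr$max_genes
  mito_bad <- mito_frac > thr$max_mito_fraction
  keep <- !(low | high | mito_bad)
  if (!any(keep)) stop("QC filtering removed all cells", call. = FALSE)
  list(
    counts = x[keep, ],
    report = list(
      n_input = nrow(x$counts),
      removed_low_genes = sum(low),
      removed_high_genes = sum(high),
      removed_mito = sum(mito_bad),
      n_retained = sum(keep),
      thresholds = unclass(thr)
    )
  )
}

#' Depth-normalize, log-transform and per-gene standardize counts
#'
#' Per cell, counts are scaled to a common library size (`target_sum`), then
#' `log1p`-transformed, then each gene column is z-scored (mean 0, SD 1)
#' across cells. Genes with zero variance map to all-zero columns. These
#' standardized values are the "scaled data" on which signature positivity
#' and the E/M score are defined.
#'
#' @param x an [emt_counts] object (normally QC-filtered).
#' @param target_sum per-cell library size after normalization.
#' @return A cells x genes numeric matrix of scaled values, with attribute
#'   `"provenance"` recording the normalization settings.
#' @export
normalize_and_scale <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "emt_counts"))
  m <- x$counts
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty count matrix", call. = FALSE)
  total <- rowSums(m)
  if (any(total == 0))
    stop("cell(s) with zero total counts; run qc_filter first", call. = FALSE)
  norm <- log1p(m / total * target_sum)
  mu <- colMeans(norm)
  sdv <- apply(norm, 2L, stats::sd)
  scaled <- sweep(norm, 2L, mu, "-")
  nz <- sdv > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2L, sdv[nz], "/")
  scaled[, !nz] <- 0
  attr(scaled, "provenance") <- list(target_sum = target_sum,
                                     log_base = exp(1), scaled = "per-gene z")
  scaled
}

#' Select cancer cells by epithelial-signature score or lineage label
#'
#' A cell is selected when its mean scaled expression over the epithelial
#' marker genes is at least `threshold`, or when its lineage-tracing flag
#' (e.g. YFP positivity established upstream by sorting) is `TRUE`. At least
#' one of the two criteria must be available.
#'
#' @param scaled cells x genes scaled matrix from [normalize_and_scale].
#' @param epithelial_markers character vector of marker gene ids (may be
#'   empty when `lineage` is given).
#' @param lineage optional logical per-cell lineage flag.
#' @param threshold selection threshold on the mean marker score (default 0,
#'   i.e. above-average epithelial expression).
#' @return A list with `cells` (selected cell ids), `by_score`, `by_lineage`
#'   (logical per input cell) and `report`.
#' @export
select_cancer_cells <- function(scaled, epithelial_markers,
                                lineage = NULL, threshold = 0) {
  markers <- intersect(epithelial_markers, colnames(scaled))
  if (length(markers) == 0L && is.null(lineage))
    stop("no epithelial markers in matrix and no lineage flags given",
         call. = FALSE)
  by_score <- if (length(markers) > 0L)
    rowMeans(scaled[, markers, drop = FALSE]) >= threshold
  else rep(FALSE, nrow(scaled))
  by_lineage <- if (is.null(lineage)) rep(FALSE, nrow(scaled)) else {
    if (length(lineage) != nrow(scaled))
      stop("lineage flags must match the number of cells", call. = FALSE)
    as.logical(lineage)
  }
  sel <- by_score | by_lineage
  if (!any(sel)) stop("no cancer cells selected", call. = FALSE)
  list(cells = rownames(scaled)[sel], by_score = by_score,
       by_lineage = by_lineage,
       report = list(n_input = nrow(scaled), n_selected = sum(sel),
                     n_by_score = sum(by_score),
                     n_by_lineage = sum(by_lineage),
                     threshold = threshold, n_markers = length(markers)))
}
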