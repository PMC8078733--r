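#' Fit the EMT spectrum of a single-cell population
#'
#' Runs the full quantification: QC filtering, depth normalization with
#' per-gene scaling, cancer-cell selection, restriction to the EMT
#' signature, Markov-diffusion (MAGIC-style) smoothing, SNN-graph
#' clustering with a data-driven resolution, per-cluster Log2(EPI/MES)
#' scoring, EMT-spectrum ordering, phenotype proportions and per-sample
#' classification.
#'
#' @param counts an [emt_counts] object (cells x genes raw counts).
#' @param signature an [emt_signature].
#' @param qc a [qc_thresholds] object, or `NULL` to skip QC.
#' @param select how cancer cells are chosen: `"signature"` scores cells on
#'   the epithelial arm (threshold `select_threshold`), `"none"` keeps all
#'   cells; a logical per-cell vector is used as a lineage-tracing flag
#'   (OR-combined with the signature score).
#' @param select_threshold threshold on the mean epithelial-marker scaled
#'   expression (default 0).
#' @param k_diffusion,decay,t diffusion-operator parameters (defaults
#'   k = 15, decay = 2, t = 3).
#' @param resolutions resolution grid for [select_resolution].
#' @param k_cluster SNN neighbour count (default 20).
#' @param quality_floor consistency floor for the resolution rule.
#' @param cutoffs a [phenotype_cutoffs] object.
#' @param sample_rule `"pooled"` or `"plurality"` for [classify_samples].
#' @param target_sum library size for depth normalization.
#' @param seed integer seed controlling the community detection.
#' @return An object of class `emt_spectrum`: list with (among others)
#'   `clusters` (ordered `em_score_table`), `assignment`, `cell_class`
#'   (per-cell phenotype via cluster class), `proportions` (overall and per
#'   sample), `samples` (per-sample classification), `smoothed` (smoothed
#'   scaled signature matrix), `qc_report`, `selection`, `discovered_count`,
#'   `params`.
#' @examples
#' pop <- simulate_emt_population(n_cells = 300, n_background_genes = 20,
#'                                seed = 2)
#' fit <- emt_spectrum(pop$counts, pop$signature, seed = 2)
#' fit
#' @export
emt_spectrum <- function(counts, signature,
                         qc = qc_thresholds(),
                         select = c("none", "signature"),
                         select_threshold = 0,
                         k_diffusion = 15, decay = 2, t = 3,
                         resolutions = c(0.25, 0.5, 1, 2),
                         k_cluster = 20,
                         quality_floor = 0.9,
                         cutoffs = phenotype_cutoffs(),
                         sample_rule = c("pooled", "plurality"),
                         target_sum = 1e4,
                         seed = 1) {
  stopifnot(inherits(counts, "emt_counts"), inherits(signature, "emt_signature"))
  sample_rule <- match.arg(sample_rule)
  cl_match <- match.call()

  # canonical cell order: results depend on the set of cells, not on the
  # order they arrive in
  counts <- counts[order(rownames(counts$counts)), ]

  # 1. QC
  if (!is.null(qc)) {
    qcres <- qc_filter(counts, qc)
    counts <- qcres$counts
    qc_report <- qcres$report
  } else qc_report <- NULL

  # 2. normalize + scale on the full gene set
  scaled <- normalize_and_scale(counts, target_sum = target_sum)

  # 3. cancer-cell selection
  lineage <- NULL
  if (is.logical(select)) {
    lineage <- select
    select_mode <- "lineage+signature"
  } else {
    select <- match.arg(select)
    select_mode <- select
  }
  if (identical(select_mode, "none")) {
    selection <- list(cells = rownames(scaled),
                      report = list(n_input = nrow(scaled),
                                    n_selected = nrow(scaled),
                                    mode = "none"))
  } else {
    selection <- select_cancer_cells(scaled, signature$epithelial_genes,
                                     lineage = lineage,
                                     threshold = select_threshold)
    selection$report$mode <- select_mode
  }
  keep <- rownames(scaled) %in% selection$cells
  counts <- counts[keep, ]
  scaled <- scaled[keep, , drop = FALSE]

  # 4. restrict to the signature and smooth
  restr <- restrict_signature(signature, colnames(scaled))
  sig <- restr$signature
  sig_genes <- c(sig$epithelial_genes, sig$mesenchymal_genes)
  x <- scaled[, sig_genes, drop = FALSE]
  op <- diffusion_operator(x, k = k_diffusion, decay = decay, t = t)
  smoothed <- smooth_expression(x, op)

  # 5. cluster with data-driven resolution
  res <- select_resolution(smoothed, resolutions = resolutions,
                           k = k_cluster, seed = seed,
                           quality_floor = quality_floor)

  # 6. score, order, proportions, samples
  tab <- score_clusters(smoothed, res$assignment, sig, cutoffs)
  ordered <- order_clusters(tab, res$assignment)
  assignment <- ordered$assignment
  tab <- ordered$table
  cell_class <- factor(
    as.character(tab$em_class)[match(assignment$cluster, tab$cluster)],
    levels = c("EPI", "PEMT", "MES"))
  names(cell_class) <- names(assignment$cluster)
  proportions <- phenotype_proportions(assignment, tab,
                                       group_by = counts$sample)
  samples <- classify_samples(smoothed, sig, counts$sample,
                              assignment = assignment, table = tab,
                              cutoffs = cutoffs, rule = sample_rule)

  structure(
    list(call = cl_match,
         clusters = tab,
         assignment = assignment,
         cell_class = cell_class,
         proportions = proportions,
         samples = samples,
         smoothed = smoothed,
         signature = sig,
         discovered_count = restr$discovered_count,
         qc_report = qc_report,
         selection = selection$report,
         resolution = res$resolution,
         resolution_log = res$log,
         resolution_rule = res$rule,
         sample_labels = counts$sample,
         cutoffs = cutoffs,
         params = list(k_diffusion = k_diffusion, decay = decay, t = t,
                       k_cluster = k_cluster, resolutions = resolutions,
                       quality_floor = quality_floor,
                       target_sum = target_sum, seed = seed,
                       sample_rule = sample_rule)),
    class = "emt_spectrum"
  )
}

#' @export
print.emt_spectrum <- function(x, ...) {
  n <- length(x$assignment$cluster)
  cat(sprintf("emt_spectrum fit: %d cells, %d clusters (resolution %g)\n",
              n, nrow(x$clusters), x$resolution))
  p <- x$proportions["overall", ]
  cat(sprintf("phenotypes: EPI %.1f%%, PEMT %.1f%%, MES %.1f%%\n",
              p["EPI"], p["PEMT"], p["MES"]))
  invisible(x)
}

#' @export
summary.emt_spectrum <- function(object, ...) {
  structure(list(fit = object), class = "summary.emt_spectrum")
}

#' @export
print.summary.emt_spectrum <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nClusters across the EMT spectrum (1 = most epithelial):\n")
  print(fit$clusters, digits = 3)
  cat("\nSamples:\n")
  print(fit$samples, digits = 3)
  cat(sprintf("\nSignature genes discoverable in the matrix: %d\n",
              fit$discovered_count))
  invisible(x)
}

#' Per-cluster E/M scores of a fitted EMT spectrum
#'
#' @param object an `emt_spectrum` fit.
#' @param ... ignored.
#' @return Named numeric of Log2(EPI/MES) scores, names the ordered cluster
#'   labels.
#' @export
coef.emt_spectrum <- function(object, ...) {
  stats::setNames(object$clusters$score, object$clusters$cluster)
}

#' Per-cell phenotype classes of a fitted EMT spectrum
#'
#' @param object an `emt_spectrum` fit.
#' @param ... ignored.
#' @return Factor (EPI/PEMT/MES) per cell, via the cell's cluster class.
#' @export
fitted.emt_spectrum <- function(object, ...) object$cell_class

#' Plot a fitted EMT spectrum
#'
#' Barplot of per-cluster Log2(EPI/MES) scores in spectrum order, coloured
#' by phenotype class, with the classification boundaries drawn as dashed
#' lines.
#'
#' @param x an `emt_spectrum` fit.
#' @param ... passed to [graphics::barplot].
#' @export
plot.emt_spectrum <- function(x, ...) {
  tab <- x$clusters
  cols <- c(EPI = "#1f77b4", PEMT = "#9467bd", MES = "#d62728")
  graphics::barplot(tab$score, names.arg = tab$cluster,
                    col = cols[as.character(tab$em_class)],
                    xlab = "cluster (EMT-spectrum order)",
                    ylab = "Log2(EPI/MES) score", border = NA, ...)
  graphics::abline(h = c(x$cutoffs$epithelial_min, x$cutoffs$mesenchymal_max),
                   lty = 2, col = "grey40")
  graphics::legend("topright", legend = names(cols), fill = cols,
                   border = NA, bty = "n")
  invisible(x)
}
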