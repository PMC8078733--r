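#' Phenotype cutoffs on the E/M score
#'
#' Default class boundaries on the Log2(EPI/MES) score: epithelial at score
#' >= 1.5, mesenchymal at score <= -1.5, partial-EMT strictly in between.
#' Both boundaries are inclusive. A small pseudocount guards zero positive
#' fractions.
#'
#' @param epithelial_min minimum score classified epithelial (default 1.5).
#' @param mesenchymal_max maximum score classified mesenchymal
#'   (default -1.5).
#' @param pseudocount small positive value added to both fractions before
#'   the ratio (default 1e-6).
#' @return A list of class `phenotype_cutoffs`.
#' @export
phenotype_cutoffs <- function(epithelial_min = 1.5, mesenchymal_max = -1.5,
                              pseudocount = 1e-6) {
  if (mesenchymal_max >= epithelial_min)
    stop("mesenchymal_max must be below epithelial_min", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  structure(list(epithelial_min = epithelial_min,
                 mesenchymal_max = mesenchymal_max,
                 pseudocount = pseudocount),
            class = "phenotype_cutoffs")
}

#' Fraction of positive scaled entries over a cell and gene subset
#'
#' "Positive" on per-gene standardized (z-scored) expression means strictly
#' greater than zero, i.e. above the gene's population mean. The fraction
#' pools all (cell, gene) entries of the subset.
#'
#' @param x cells x genes scaled matrix.
#' @param cells cell ids or indices (non-empty).
#' @param genes gene ids or indices (non-empty).
#' @return The fraction of entries > 0, in \[0, 1\].
#' @export
positive_fraction <- function(x, cells, genes) {
  if (length(cells) == 0L) stop("empty cell subset", call. = FALSE)
  if (length(genes) == 0L) stop("empty gene set", call. = FALSE)
  sub <- x[cells, genes, drop = FALSE]
  mean(sub > 0)
}

#' Compute the Log2(EPI/MES) E/M score and phenotype class
#'
#' `score = log2((EPI + pseudocount) / (MES + pseudocount))` where EPI and
#' MES are the positive fractions of the epithelial and mesenchymal
#' signature arms on scaled data. Classification follows the cutoffs:
#' score >= 1.5 epithelial (EPI), score <= -1.5 mesenchymal (MES),
#' otherwise partial-EMT (PEMT); boundaries inclusive. Vectorized.
#'
#' @param epi_fraction,mes_fraction positive fractions in \[0, 1\]
#'   (recycled to a common length).
#' @param cutoffs a [phenotype_cutoffs] object.
#' @return Data frame with columns `score` and `em_class`
#'   (factor EPI / PEMT / MES).
#' @examples
#' em_score(0.8, 0.1)   # log2(8) = 3 -> EPI
#' em_score(0.4, 0.4)   # 0 -> PEMT
#' @export
em_score <- function(epi_fraction, mes_fraction,
                     cutoffs = phenotype_cutoffs()) {
  if (any(epi_fraction < 0 | epi_fraction > 1) ||
      any(mes_fraction < 0 | mes_fraction > 1))
    stop("fractions must be in [0, 1]", call. = FALSE)
  pc <- cutoffs$pseudocount
  score <- log2((epi_fraction + pc) / (mes_fraction + pc))
  data.frame(score = score, em_class = classify_em_score(score, cutoffs))
}

#' Classify an E/M score into a phenotype
#'
#' Applies the class boundaries to a Log2(EPI/MES) score: score >= 1.5 is
#' epithelial, score <= -1.5 mesenchymal, strictly in between partial-EMT
#' (defaults; boundaries inclusive). Vectorized.
#'
#' @param score numeric E/M scores.
#' @param cutoffs a [phenotype_cutoffs] object.
#' @return Factor with levels EPI, PEMT, MES.
#' @export
classify_em_score <- function(score, cutoffs = phenotype_cutoffs()) {
  cls <- ifelse(score >= cutoffs$epithelial_min, "EPI",
                ifelse(score <= cutoffs$mesenchymal_max, "MES", "PEMT"))
  factor(cls, levels = c("EPI", "PEMT", "MES"))
}

#' Score and classify every cluster along the EMT continuum
#'
#' For each cluster, computes the positive fractions of the two signature
#' arms over the cluster's (cell, gene) entries of the scaled matrix, the
#' Log2(EPI/MES) score and the phenotype class.
#'
#' @param x cells x genes scaled (typically diffusion-smoothed) matrix.
#' @param assignment a [cluster_cells] result (or an integer vector of
#'   cluster labels per cell).
#' @param signature an [emt_signature]; genes absent from `x` are ignored
#'   (both arms must remain represented).
#' @param cutoffs a [phenotype_cutoffs] object.
#' @return Data frame of class `em_score_table`: `cluster`, `epi_fraction`,
#'   `mes_fraction`, `score`, `em_class`, `n_cells`.
#' @export
score_clusters <- function(x, assignment, signature,
                           cutoffs = phenotype_cutoffs()) {
  cl <- if (inherits(assignment, "cluster_assignment"))
    assignment$cluster else as.integer(assignment)
  if (length(cl) != nrow(x))
    stop("assignment length must match the number of cells", call. = FALSE)
  sig <- restrict_signature(signature, colnames(x))$signature
  labs <- sort(unique(cl))
  epi <- vapply(labs, function(c0)
    positive_fraction(x, which(cl == c0), sig$epithelial_genes), numeric(1))
  mes <- vapply(labs, function(c0)
    positive_fraction(x, which(cl == c0), sig$mesenchymal_genes), numeric(1))
  sc <- em_score(epi, mes, cutoffs)
  out <- data.frame(cluster = labs, epi_fraction = epi, mes_fraction = mes,
                    score = sc$score, em_class = sc$em_class,
                    n_cells = as.integer(table(factor(cl, levels = labs))))
  class(out) <- c("em_score_table", "data.frame")
  out
}

#' Order clusters across the EMT spectrum
#'
#' Relabels clusters 1..K in strictly decreasing E/M-score order, so
#' cluster 1 is the most epithelial and cluster K the most mesenchymal.
#' Ties are broken by larger cluster size, then by original label. Cell
#' assignments, if supplied, are remapped consistently.
#'
#' @param table an `em_score_table` from [score_clusters].
#' @param assignment optional [cluster_cells] result to remap.
#' @return A list with `table` (relabeled, sorted) and `assignment`
#'   (remapped, or `NULL`).
#' @export
order_clusters <- function(table, assignment = NULL) {
  if (nrow(table) == 0) stop("empty score table", call. = FALSE)
  ord <- order(-table$score, -table$n_cells, table$cluster)
  new_of_old <- integer(max(table$cluster))
  new_of_old[table$cluster[ord]] <- seq_along(ord)
  out <- table[ord, , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("em_score_table", "data.frame")
  if (!is.null(assignment)) {
    cl <- if (inherits(assignment, "cluster_assignment"))
      assignment$cluster else as.integer(assignment)
    remapped <- new_of_old[cl]
    names(remapped) <- names(cl)
    if (inherits(assignment, "cluster_assignment")) {
      assignment$cluster <- remapped
    } else assignment <- remapped
  }
  list(table = out, assignment = assignment)
}

#' Cell-weighted phenotype proportions
#'
#' Percentage of cells falling in clusters of each phenotype class, overall
#' and optionally per group (e.g. per sample). Percentages sum to 100.
#'
#' @param assignment a [cluster_cells] result or integer labels per cell.
#' @param table an `em_score_table` classifying every cluster.
#' @param group_by optional per-cell grouping labels.
#' @return A named numeric (EPI, PEMT, MES) of percentages, or, with
#'   `group_by`, a matrix with one row per group plus an `"overall"` row.
#' @export
phenotype_proportions <- function(assignment, table, group_by = NULL) {
  cl <- if (inherits(assignment, "cluster_assignment"))
    assignment$cluster else as.integer(assignment)
  cls_of_cluster <- as.character(table$em_class)[match(cl, table$cluster)]
  if (anyNA(cls_of_cluster))
    stop("every cluster must be classified in the score table", call. = FALSE)
  lv <- c("EPI", "PEMT", "MES")
  prop <- function(v) 100 * table(factor(v, levels = lv)) / length(v)
  overall <- as.numeric(prop(cls_of_cluster))
  names(overall) <- lv
  if (is.null(group_by)) return(overall)
  if (length(group_by) != length(cl))
    stop("group_by must match the number of cells", call. = FALSE)
  groups <- sort(unique(as.character(group_by)))
  m <- t(vapply(groups, function(g)
    as.numeric(prop(cls_of_cluster[group_by == g])), numeric(3)))
  colnames(m) <- lv
  rbind(m, overall = overall)
}

#' Classify whole samples along the EMT continuum
#'
#' Default rule (`"pooled"`): pool each sample's cells, compute the positive
#' fractions of both signature arms over the pool, and classify the pooled
#' Log2(EPI/MES) score with the same cutoffs used for clusters. Alternative
#' rule (`"plurality"`): assign the sample the most common per-cell class,
#' where each cell inherits its cluster's class (ties broken toward the
#' more epithelial class).
#'
#' @param x cells x genes scaled (smoothed) matrix.
#' @param signature an [emt_signature].
#' @param sample per-cell sample labels.
#' @param assignment a [cluster_cells] result (needed for `"plurality"`).
#' @param table an `em_score_table` (needed for `"plurality"`).
#' @param cutoffs a [phenotype_cutoffs] object.
#' @param rule `"pooled"` (default) or `"plurality"`.
#' @return Data frame `sample_id`, `score` (NA under plurality),
#'   `em_class`, `n_cells`, `rule`.
#' @export
classify_samples <- function(x, signature, sample, assignment = NULL,
                             table = NULL, cutoffs = phenotype_cutoffs(),
                             rule = c("pooled", "plurality")) {
  rule <- match.arg(rule)
  sample <- as.character(sample)
  if (length(sample) != nrow(x))
    stop("sample labels must match the number of cells", call. = FALSE)
  ids <- sort(unique(sample))
  if (rule == "pooled") {
    sig <- restrict_signature(signature, colnames(x))$signature
    epi <- vapply(ids, function(s)
      positive_fraction(x, which(sample == s), sig$epithelial_genes),
      numeric(1))
    mes <- vapply(ids, function(s)
      positive_fraction(x, which(sample == s), sig$mesenchymal_genes),
      numeric(1))
    sc <- em_score(epi, mes, cutoffs)
    out <- data.frame(sample_id = ids, score = sc$score,
                      em_class = sc$em_class, stringsAsFactors = FALSE)
  } else {
    if (is.null(assignment) || is.null(table))
      stop("plurality rule needs assignment and score table", call. = FALSE)
    cl <- if (inherits(assignment, "cluster_assignment"))
      assignment$cluster else as.integer(assignment)
    cell_class <- factor(as.character(table$em_class)[match(cl, table$cluster)],
                         levels = c("EPI", "PEMT", "MES"))
    out <- data.frame(
      sample_id = ids,
      score = NA_real_,
      em_class = factor(vapply(ids, function(s) {
        tab <- table(cell_class[sample == s])
        names(tab)[which.max(tab)]  # which.max takes the first (most
      }, character(1)), levels = c("EPI", "PEMT", "MES")),  # epithelial) tie
      stringsAsFactors = FALSE)
  }
  out$n_cells <- as.integer(table(factor(sample, levels = ids)))
  out$rule <- rule
  rownames(out) <- NULL
  out
}
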