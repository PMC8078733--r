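#' Construct a cells-by-genes count matrix container
#'
#' Bundles a non-negative cells x genes count matrix with per-cell sample
#' labels and per-gene mitochondrial flags. Rows are cells, columns genes;
#' row and column names are the identifiers and must be unique.
#'
#' @param counts numeric cells x genes matrix, non-negative, with unique
#'   rownames (cell ids) and colnames (gene ids).
#' @param sample character/factor of per-cell sample labels (recycled if
#'   length 1); defaults to a single sample `"S1"`.
#' @param mito logical per-gene mitochondrial flag; if `NULL`, derived from
#'   `mito_prefix` on the gene ids (case-insensitive).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return An object of class `emt_counts`.
#' @export
emt_counts <- function(counts, sample = NULL, mito = NULL, mito_prefix = "MT-") {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("cell ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("gene ids must be unique", call. = FALSE)
  if (is.null(sample)) sample <- "S1"
  sample <- as.character(sample)
  if (length(sample) == 1L) sample <- rep(sample, nrow(counts))
  if (length(sample) != nrow(counts))
    stop("sample labels must match the number of cells", call. = FALSE)
  if (is.null(mito)) {
    mito <- startsWith(toupper(colnames(counts)), toupper(mito_prefix))
  }
  if (length(mito) != ncol(counts))
    stop("mito flags must match the number of genes", call. = FALSE)
  structure(
    list(counts = counts, sample = sample, mito = as.logical(mito)),
    class = "emt_counts"
  )
}

#' @export
print.emt_counts <- function(x, ...) {
  cat(sprintf("emt_counts: %d cells x %d genes (%d mitochondrial), %d sample(s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito),
              length(unique(x$sample))))
  invisible(x)
}

#' @export
dim.emt_counts <- function(x) dim(x$counts)

#' Subset an emt_counts object by cells and/or genes
#'
#' @param x an [emt_counts] object.
#' @param i cell index (logical, integer or cell ids).
#' @param j gene index (logical, integer or gene ids).
#' @param ... ignored.
#' @return An [emt_counts] with the selected cells/genes.
#' @export
`[.emt_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, rownames(x$counts))
  if (is.character(j)) j <- match(j, colnames(x$counts))
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  emt_counts(x$counts[i, j, drop = FALSE], sample = x$sample[i],
             mito = x$mito[j])
}

#' Write a count matrix as MatrixMarket MTX with TSV sidecars
#'
#' Writes `matrix.mtx` (cells x genes, sparse MatrixMarket), `genes.tsv`
#' (gene_id, mito) and `cells.tsv` (cell_id, sample) into `dir`.
#'
#' @param x an [emt_counts] object.
#' @param dir output directory; created if needed.
#' @return `dir`, invisibly.
#' @export
write_emt_counts <- function(x, dir) {
  stopifnot(inherits(x, "emt_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(gene_id = colnames(x$counts), mito = x$mito),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = rownames(x$counts), sample = x$sample),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_emt_counts]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return An [emt_counts] object.
#' @export
read_emt_counts <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  rownames(m) <- cells$cell_id
  colnames(m) <- genes$gene_id
  emt_counts(m, sample = cells$sample, mito = as.logical(genes$mito))
}
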