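#' Construct an EMT gene signature
#'
#' An EMT signature is two disjoint, non-empty sets of gene symbols: an
#' epithelial arm (genes high at the epithelial pole) and a mesenchymal arm
#' (genes high at the mesenchymal pole). The Log2(EPI/MES) score is defined
#' with respect to these two arms.
#'
#' @param epithelial_genes character vector of epithelial-arm gene symbols.
#' @param mesenchymal_genes character vector of mesenchymal-arm gene symbols.
#' @param name optional label for the signature.
#' @return An object of class `emt_signature` with elements
#'   `epithelial_genes`, `mesenchymal_genes`, `name`.
#' @examples
#' sig <- emt_signature(c("CDH1", "EPCAM"), c("VIM", "ZEB1"))
#' length(sig)
#' @export
emt_signature <- function(epithelial_genes, mesenchymal_genes, name = "custom") {
  epithelial_genes <- as.character(epithelial_genes)
  mesenchymal_genes <- as.character(mesenchymal_genes)
  if (anyDuplicated(epithelial_genes))
    epithelial_genes <- unique(epithelial_genes)
  if (anyDuplicated(mesenchymal_genes))
    mesenchymal_genes <- unique(mesenchymal_genes)
  if (length(epithelial_genes) == 0L || length(mesenchymal_genes) == 0L)
    stop("both signature arms must be non-empty", call. = FALSE)
  both <- intersect(epithelial_genes, mesenchymal_genes)
  if (length(both) > 0L)
    stop("gene(s) present in both arms: ", paste(both, collapse = ", "),
         call. = FALSE)
  structure(
    list(epithelial_genes = epithelial_genes,
         mesenchymal_genes = mesenchymal_genes,
         name = as.character(name)[1L]),
    class = "emt_signature"
  )
}

#' @export
print.emt_signature <- function(x, ...) {
  cat(sprintf("EMT signature '%s': %d epithelial + %d mesenchymal genes\n",
              x$name, length(x$epithelial_genes), length(x$mesenchymal_genes)))
  invisible(x)
}

#' @export
length.emt_signature <- function(x) {
  length(x$epithelial_genes) + length(x$mesenchymal_genes)
}

#' Read an EMT signature from a two-column TSV file
#'
#' The file must have a header with columns `gene` and `arm`, where `arm` is
#' `"epithelial"` or `"mesenchymal"`. Duplicate rows are collapsed; a symbol
#' listed in both arms is an error.
#'
#' @param path path to the signature TSV.
#' @param name label for the signature; defaults to the file name.
#' @return An [emt_signature] object.
#' @export
read_emt_signature <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "arm") %in% names(tab)))
    stop("signature file must have columns 'gene' and 'arm': ", path,
         call. = FALSE)
  bad <- setdiff(unique(tab$arm), c("epithelial", "mesenchymal"))
  if (length(bad) > 0L)
    stop("unknown arm label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  emt_signature(tab$gene[tab$arm == "epithelial"],
                tab$gene[tab$arm == "mesenchymal"],
                name = name)
}

#' Write an EMT signature as a two-column TSV file
#'
#' @param sig an [emt_signature].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_emt_signature <- function(sig, path) {
  stopifnot(inherits(sig, "emt_signature"))
  tab <- data.frame(
    gene = c(sig$epithelial_genes, sig$mesenchymal_genes),
    arm = rep(c("epithelial", "mesenchymal"),
              c(length(sig$epithelial_genes), length(sig$mesenchymal_genes))),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a signature to the genes present in a matrix
#'
#' Drops signature genes that are not in the supplied gene universe and
#' reports how many signature genes were discoverable. Errors if either arm
#' would become empty. Idempotent.
#'
#' @param sig an [emt_signature].
#' @param genes character vector of gene identifiers (the matrix universe).
#' @return A list with `signature` (the restricted [emt_signature]) and
#'   `discovered_count` (number of signature genes found in the universe).
#' @export
restrict_signature <- function(sig, genes) {
  stopifnot(inherits(sig, "emt_signature"))
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene universe is empty", call. = FALSE)
  epi <- sig$epithelial_genes[sig$epithelial_genes %in% genes]
  mes <- sig$mesenchymal_genes[sig$mesenchymal_genes %in% genes]
  if (length(epi) == 0L)
    stop("no epithelial-arm gene present in the matrix", call. = FALSE)
  if (length(mes) == 0L)
    stop("no mesenchymal-arm gene present in the matrix", call. = FALSE)
  list(signature = emt_signature(epi, mes, name = sig$name),
       discovered_count = length(epi) + length(mes))
}

#' Map a signature between species via an ortholog table or casing rule
#'
#' Translates gene symbols of a signature to another species. Either supply a
#' two-column ortholog table (`human_symbol`, `mouse_symbol`) or use the
#' `"title-case"` rule, the common human-to-mouse symbol convention
#' (`CDH1 -> Cdh1`). Genes without a mapping are recorded and dropped; arm
#' membership is preserved.
#'
#' @param sig an [emt_signature].
#' @param table optional data frame with columns `human_symbol`,
#'   `mouse_symbol` (or a path to such a TSV). If `NULL`, `rule` is used.
#' @param rule mapping rule when no table is given; only `"title-case"`.
#' @return A list with `signature` (mapped [emt_signature]) and `map`
#'   (list with `pairs`, a named character vector source -> target, and
#'   `unmapped`, the source symbols without a target).
#' @export
map_orthologs <- function(sig, table = NULL, rule = "title-case") {
  stopifnot(inherits(sig, "emt_signature"))
  src <- c(sig$epithelial_genes, sig$mesenchymal_genes)
  arm <- rep(c("epithelial", "mesenchymal"),
             c(length(sig$epithelial_genes), length(sig$mesenchymal_genes)))
  if (is.null(table)) {
    rule <- match.arg(rule, "title-case")
    target <- paste0(substr(src, 1L, 1L), tolower(substring(src, 2L)))
    names(target) <- src
    mapped <- rep(TRUE, length(src))
  } else {
    if (is.character(table) && length(table) == 1L)
      table <- utils::read.delim(table, stringsAsFactors = FALSE)
    if (!all(c("human_symbol", "mouse_symbol") %in% names(table)))
      stop("ortholog table must have columns 'human_symbol' and 'mouse_symbol'",
           call. = FALSE)
    if (anyDuplicated(table$human_symbol))
      stop("each source symbol must map to at most one target", call. = FALSE)
    idx <- match(src, table$human_symbol)
    mapped <- !is.na(idx)
    target <- table$mouse_symbol[idx]
    names(target) <- src
  }
  # two sources collapsing onto one target from different arms is incoherent
  tgt_arm <- split(arm[mapped], target[mapped])
  conflict <- names(tgt_arm)[vapply(tgt_arm, function(a) length(unique(a)) > 1L,
                                    logical(1))]
  if (length(conflict) > 0L)
    stop("conflicting arm membership for mapped symbol(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  epi <- unname(target[mapped & arm == "epithelial"])
  mes <- unname(target[mapped & arm == "mesenchymal"])
  if (length(epi) == 0L || length(mes) == 0L)
    stop("ortholog mapping left an arm empty", call. = FALSE)
  list(
    signature = emt_signature(unique(epi), unique(mes), name = sig$name),
    map = list(pairs = target[mapped], unmapped = src[!mapped])
  )
}
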