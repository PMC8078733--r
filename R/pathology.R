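#' Weighted histopathology scoring rules
#'
#' Each rule adds a fixed weight when the (aggregated) percentage of a
#' histology category strictly exceeds its threshold: normal > 5% adds 1,
#' PanIN > 30% adds 2, PDAC (well- plus moderately-differentiated) > 30%
#' adds 4, poorly-differentiated PDAC > 5% adds 5, necrosis > 5% adds 6.
#' Whether poorly-differentiated PDAC also counts toward the PDAC aggregate
#' is configurable (off by default, since it carries its own rule).
#'
#' @param include_poor_in_pdac logical; add `pdac_poor` to the PDAC > 30%
#'   aggregate (default `FALSE`).
#' @return Data frame of class `pathology_weights` with columns `rule`,
#'   `categories` (list), `threshold`, `weight`.
#' @export
pathology_weights <- function(include_poor_in_pdac = FALSE) {
  pdac_cats <- c("pdac_well", "pdac_moderate",
                 if (include_poor_in_pdac) "pdac_poor")
  out <- data.frame(
    rule = c("normal", "panin", "pdac", "pdac_poor", "necrosis"),
    threshold = c(5, 30, 30, 5, 5),
    weight = c(1L, 2L, 4L, 5L, 6L),
    stringsAsFactors = FALSE
  )
  out$categories <- list("normal", "panin", pdac_cats, "pdac_poor",
                         "necrosis")
  class(out) <- c("pathology_weights", "data.frame")
  out
}

histology_categories <- c("normal", "panin", "pdac_well", "pdac_moderate",
                          "pdac_poor", "necrosis")

validate_composition <- function(comp) {
  comp <- unlist(comp[histology_categories])
  if (anyNA(comp))
    stop("composition must contain the six categories: ",
         paste(histology_categories, collapse = ", "), call. = FALSE)
  if (any(comp < 0)) stop("negative percentage in composition", call. = FALSE)
  if (any(comp > 100)) stop("percentage above 100 in composition",
                            call. = FALSE)
  if (sum(comp) > 100 + 1e-9)
    stop("composition percentages sum above 100", call. = FALSE)
  comp
}

#' Weighted pathology score of one specimen composition
#'
#' Sums the rule weights for every scoring rule whose aggregated category
#' percentage strictly exceeds its threshold.
#'
#' @param composition named numeric (or one-row data frame) of percentages
#'   for `normal`, `panin`, `pdac_well`, `pdac_moderate`, `pdac_poor`,
#'   `necrosis`; non-negative, summing to at most 100.
#' @param weights a [pathology_weights] rule table.
#' @return Integer score (0 up to the sum of all weights, 18 by default).
#' @examples
#' weighted_pathology_score(c(normal = 0, panin = 100, pdac_well = 0,
#'                            pdac_moderate = 0, pdac_poor = 0, necrosis = 0))
#' @export
weighted_pathology_score <- function(composition,
                                     weights = pathology_weights()) {
  comp <- validate_composition(composition)
  fired <- vapply(seq_len(nrow(weights)), function(i) {
    sum(comp[weights$categories[[i]]]) > weights$threshold[i]
  }, logical(1))
  as.integer(sum(weights$weight[fired]))
}

#' Score a table of specimen compositions
#'
#' @param table data frame with `specimen_id` (optional) and the six
#'   histology percentage columns.
#' @param weights a [pathology_weights] rule table.
#' @return Data frame `specimen_id`, `score`.
#' @export
score_histology <- function(table, weights = pathology_weights()) {
  ids <- if ("specimen_id" %in% names(table)) table$specimen_id
         else sprintf("spec%03d", seq_len(nrow(table)))
  scores <- vapply(seq_len(nrow(table)), function(i)
    weighted_pathology_score(table[i, , drop = FALSE], weights), integer(1))
  data.frame(specimen_id = ids, score = scores, stringsAsFactors = FALSE)
}
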