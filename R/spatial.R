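#' Construct a marked point pattern
#'
#' A set of 2-D points in micrometres with a phenotype mark per point,
#' inside an axis-aligned rectangular observation window.
#'
#' @param x,y numeric coordinates in micrometres.
#' @param phenotype character/factor mark per point.
#' @param window numeric `c(xmin, xmax, ymin, ymax)`; all points must lie
#'   inside.
#' @return An object of class `point_pattern`: list with `points` (data
#'   frame `x_um`, `y_um`, `phenotype`) and `window`.
#' @export
point_pattern <- function(x, y, phenotype, window) {
  window <- as.numeric(window)
  if (length(window) != 4L || window[2] <= window[1] || window[4] <= window[3])
    stop("window must be c(xmin, xmax, ymin, ymax) with positive area",
         call. = FALSE)
  if (length(x) != length(y) || length(x) != length(phenotype))
    stop("x, y and phenotype must have equal length", call. = FALSE)
  if (any(x < window[1] | x > window[2] | y < window[3] | y > window[4]))
    stop("all points must lie inside the window", call. = FALSE)
  structure(
    list(points = data.frame(x_um = x, y_um = y,
                             phenotype = as.character(phenotype),
                             stringsAsFactors = FALSE),
         window = window),
    class = "point_pattern"
  )
}

#' @export
print.point_pattern <- function(x, ...) {
  tab <- table(x$points$phenotype)
  cat(sprintf("point_pattern: %d points in [%g, %g] x [%g, %g] um (%s)\n",
              nrow(x$points), x$window[1], x$window[2], x$window[3],
              x$window[4],
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Read a point pattern from CSV
#'
#' The file must have labelled columns `x_um`, `y_um`, `phenotype`
#' (unlabelled coordinate columns are rejected — units matter).
#'
#' @param path CSV path.
#' @param window optional window; defaults to the bounding box of the
#'   points.
#' @return A [point_pattern].
#' @export
read_point_pattern <- function(path, window = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "phenotype")
  if (!all(need %in% names(tab)))
    stop("point CSV must have columns x_um, y_um, phenotype (micrometres)",
         call. = FALSE)
  if (is.null(window))
    window <- c(min(tab$x_um), max(tab$x_um), min(tab$y_um), max(tab$y_um))
  point_pattern(tab$x_um, tab$y_um, tab$phenotype, window)
}

#' Write a point pattern to CSV
#'
#' @param pattern a [point_pattern].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  utils::write.csv(pattern$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

window_area <- function(w) (w[2] - w[1]) * (w[4] - w[3])

cross_dists <- function(pattern, from_mark, to_mark) {
  p <- pattern$points
  from <- p[p$phenotype == from_mark, c("x_um", "y_um"), drop = FALSE]
  to <- p[p$phenotype == to_mark, c("x_um", "y_um"), drop = FALSE]
  if (nrow(from) == 0L) stop("no points with mark '", from_mark, "'",
                             call. = FALSE)
  if (nrow(to) == 0L) stop("no points with mark '", to_mark, "'",
                           call. = FALSE)
  dx <- outer(from$x_um, to$x_um, "-")
  dy <- outer(from$y_um, to$y_um, "-")
  list(d = sqrt(dx^2 + dy^2), dx = dx, dy = dy,
       n_from = nrow(from), n_to = nrow(to))
}

#' Bivariate Ripley K function between two phenotypes
#'
#' Estimates, for each radius r, `K(r) = |W| / (n_from * n_to) *
#' sum_ij w_ij 1[d_ij <= r]` over ordered pairs of a from-mark point and a
#' to-mark point. With `edge_correction = "none"` all weights are 1; with
#' `"translation"` each pair is weighted by `|W| / |W intersect W_shifted|`,
#' the standard translation edge correction for rectangular windows.
#'
#' @param pattern a [point_pattern].
#' @param from_mark,to_mark phenotype marks.
#' @param radii strictly increasing positive radii (micrometres), at most
#'   half the shorter window side.
#' @param edge_correction `"none"` (default) or `"translation"`.
#' @return Numeric vector of K estimates, one per radius.
#' @export
bivariate_k <- function(pattern, from_mark, to_mark, radii,
                        edge_correction = c("none", "translation")) {
  edge_correction <- match.arg(edge_correction)
  stopifnot(inherits(pattern, "point_pattern"))
  radii <- as.numeric(radii)
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing and positive", call. = FALSE)
  w <- pattern$window
  half_short <- min(w[2] - w[1], w[4] - w[3]) / 2
  if (max(radii) > half_short)
    stop("largest radius exceeds half the shorter window side",
         call. = FALSE)
  cd <- cross_dists(pattern, from_mark, to_mark)
  area <- window_area(w)
  wt <- if (edge_correction == "none") 1 else {
    area / ((w[2] - w[1] - abs(cd$dx)) * (w[4] - w[3] - abs(cd$dy)))
  }
  vapply(radii, function(r)
    area / (cd$n_from * cd$n_to) * sum(wt * (cd$d <= r)), numeric(1))
}

#' L function from K values
#'
#' The variance-stabilized transform `L(r) = sqrt(K(r) / pi)`; under
#' complete spatial randomness `L(r) = r`.
#'
#' @param k non-negative K estimates.
#' @return L values of the same length.
#' @export
l_from_k <- function(k) {
  if (any(k < 0)) stop("K values must be non-negative", call. = FALSE)
  sqrt(k / pi)
}

#' L-curve and area under the curve up to a contact radius
#'
#' Computes the bivariate L function on a uniform radius grid over
#' `(0, r_max]` and its trapezoidal area under the curve — the infiltration
#' statistic summarizing how many neighbour-phenotype cells surround the
#' reference phenotype within `r_max` (20 um by default, cell-cell contact
#' distance).
#'
#' @param pattern a [point_pattern].
#' @param from_mark reference phenotype (default `"cancer"`).
#' @param to_mark neighbour phenotype (default `"tcell"`).
#' @param r_max maximum radius in micrometres (default 20).
#' @param n_radii grid size (default 40).
#' @param edge_correction passed to [bivariate_k].
#' @return An object of class `l_curve`: list with `radii`, `l_values`,
#'   `auc`, `reference_phenotype`, `neighbor_phenotype`, `edge_correction`.
#' @export
l_auc <- function(pattern, from_mark = "cancer", to_mark = "tcell",
                  r_max = 20, n_radii = 40,
                  edge_correction = c("none", "translation")) {
  edge_correction <- match.arg(edge_correction)
  if (r_max <= 0) stop("r_max must be positive", call. = FALSE)
  radii <- seq(r_max / n_radii, r_max, length.out = n_radii)
  k <- bivariate_k(pattern, from_mark, to_mark, radii,
                   edge_correction = edge_correction)
  l <- l_from_k(k)
  auc <- sum(diff(radii) * (utils::head(l, -1) + utils::tail(l, -1)) / 2)
  structure(
    list(radii = radii, l_values = l, auc = auc,
         reference_phenotype = from_mark, neighbor_phenotype = to_mark,
         edge_correction = edge_correction),
    class = "l_curve"
  )
}

#' @export
print.l_curve <- function(x, ...) {
  cat(sprintf(
    "L-curve %s -> %s: %d radii up to %g um, AUC = %.3f (edge: %s)\n",
    x$reference_phenotype, x$neighbor_phenotype, length(x$radii),
    max(x$radii), x$auc, x$edge_correction))
  invisible(x)
}

#' @export
plot.l_curve <- function(x, ...) {
  graphics::plot(x$radii, x$l_values, type = "l",
                 xlab = "r (um)", ylab = "L(r)", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Neighbour counts within a contact radius
#'
#' For every from-mark point, the number of to-mark points within `radius`
#' micrometres, plus the mean count — e.g. T cells within 20 um of each
#' cancer cell.
#'
#' @param pattern a [point_pattern].
#' @param from_mark,to_mark phenotype marks.
#' @param radius contact radius in micrometres (> 0).
#' @return A list with `counts` (integer per from-mark point) and `mean`.
#' @export
contact_counts <- function(pattern, from_mark, to_mark, radius) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  cd <- cross_dists(pattern, from_mark, to_mark)
  counts <- as.integer(rowSums(cd$d <= radius))
  list(counts = counts, mean = mean(counts))
}
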