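#' Simulate a single-cell population spread along the EMT continuum
#'
#' Generates negative-binomial scRNA-seq counts with dropout for a mixture of
#' epithelial (EPI), partial-EMT (PEMT) and mesenchymal (MES) cells, together
#' with the EMT signature the expression was built from and the per-cell
#' ground truth. Each cell carries a latent EMT coordinate in \[0, 1\]
#' (0 = epithelial pole, 1 = mesenchymal pole) drawn from class-specific
#' bands: EPI ~ U(0, 0.25), PEMT ~ U(0.35, 0.65), MES ~ U(0.75, 1). The gap
#' between bands makes ground-truth class membership unambiguous.
#'
#' Each signature gene switches between a low and a high expression level
#' along the latent axis through a logistic profile: epithelial-arm genes
#' decrease with the latent coordinate, mesenchymal-arm genes increase.
#' Within each arm, half of the genes switch at the epithelial-to-partial
#' transition and half at the partial-to-mesenchymal transition, so
#' partial-EMT cells co-express roughly half of each program — the hybrid
#' co-expression structure that defines partial EMT and that the
#' Log2(EPI/MES) positive-fraction score resolves: the score plateaus near
#' +3/0/-3 on the three bands. Counts are NB(mu, size = `dispersion`) on
#' cell-specific library sizes, with Bernoulli dropout applied per entry.
#' Mitochondrial genes are constant-rate genes named with `mito_prefix`,
#' scaled to a target share of the library so QC behaviour is controllable.
#'
#' @param n_cells number of cells (>= 10).
#' @param n_epi_genes,n_mes_genes number of epithelial / mesenchymal
#'   signature genes (>= 1).
#' @param n_background_genes,n_mito_genes number of non-signature background
#'   and mitochondrial genes (>= 0).
#' @param mixture_weights length-3 non-negative numeric (EPI, PEMT, MES)
#'   summing to 1.
#' @param mean_depth expected library size (counts per cell).
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param dropout_rate per-entry probability of zeroing a sampled count,
#'   in \[0, 1).
#' @param mito_fraction expected share of the library from mitochondrial
#'   genes (used only when `n_mito_genes > 0`).
#' @param n_samples number of sample labels; cells are split evenly.
#' @param sample_weights optional `n_samples` x 3 matrix of per-sample
#'   mixture weights (rows sum to 1) overriding `mixture_weights`, e.g. to
#'   draw whole samples from a single class band.
#' @param mito_prefix name prefix for mitochondrial genes.
#' @param seed integer seed; the output is deterministic given the seed.
#' @return A list with elements
#'   \describe{
#'     \item{counts}{an [emt_counts] object (cells x genes).}
#'     \item{signature}{the generating [emt_signature].}
#'     \item{truth}{data frame `cell_id`, `latent_emt`, `true_class`,
#'       `sample_id`.}
#'     \item{mu}{the noise-free expected count matrix (before dropout).}
#'   }
#' @examples
#' pop <- simulate_emt_population(n_cells = 100, seed = 1)
#' table(pop$truth$true_class)
#' @export
simulate_emt_population <- function(n_cells = 3000,
                                    n_epi_genes = 60,
                                    n_mes_genes = 60,
                                    n_background_genes = 400,
                                    n_mito_genes = 10,
                                    mixture_weights = c(0.4, 0.35, 0.25),
                                    mean_depth = 2000,
                                    dispersion = 2,
                                    dropout_rate = 0.3,
                                    mito_fraction = 0.05,
                                    n_samples = 1,
                                    sample_weights = NULL,
                                    mito_prefix = "MT-",
                                    seed = 1) {
  if (n_cells < 10) stop("n_cells must be at least 10", call. = FALSE)
  if (n_epi_genes < 1 || n_mes_genes < 1)
    stop("each signature arm needs at least one gene", call. = FALSE)
  if (n_background_genes < 0 || n_mito_genes < 0)
    stop("gene counts must be non-negative", call. = FALSE)
  mixture_weights <- as.numeric(mixture_weights)
  if (length(mixture_weights) != 3L || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-12)
    stop("mixture_weights must be 3 non-negative values summing to 1",
         call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (!is.null(sample_weights)) {
    sample_weights <- as.matrix(sample_weights)
    if (nrow(sample_weights) != n_samples || ncol(sample_weights) != 3L)
      stop("sample_weights must be an n_samples x 3 matrix", call. = FALSE)
    if (any(abs(rowSums(sample_weights) - 1) > 1e-12))
      stop("sample_weights rows must sum to 1", call. = FALSE)
  }
  set.seed(as.integer(seed))

  sample_id <- rep(paste0("S", seq_len(n_samples)), length.out = n_cells)
  sample_id <- sort(sample_id)
  classes <- c("EPI", "PEMT", "MES")
  if (is.null(sample_weights)) {
    true_class <- sample(classes, n_cells, replace = TRUE,
                         prob = mixture_weights)
  } else {
    true_class <- character(n_cells)
    for (s in seq_len(n_samples)) {
      idx <- which(sample_id == paste0("S", s))
      true_class[idx] <- sample(classes, length(idx), replace = TRUE,
                                prob = sample_weights[s, ])
    }
  }
  # latent EMT coordinate drawn from disjoint class bands
  bands <- list(EPI = c(0, 0.25), PEMT = c(0.35, 0.65), MES = c(0.75, 1))
  latent <- vapply(true_class, function(cl) {
    b <- bands[[cl]]
    stats::runif(1, b[1], b[2])
  }, numeric(1))
  names(latent) <- NULL

  epi_genes <- sprintf("EPI%03d", seq_len(n_epi_genes))
  mes_genes <- sprintf("MES%03d", seq_len(n_mes_genes))
  bg_genes <- if (n_background_genes > 0)
    sprintf("BG%03d", seq_len(n_background_genes)) else character(0)
  mito_genes <- if (n_mito_genes > 0)
    sprintf("%s%d", mito_prefix, seq_len(n_mito_genes)) else character(0)
  genes <- c(epi_genes, mes_genes, bg_genes, mito_genes)

  # logistic switch profiles: each gene crosses from high to low (epithelial
  # arm) or low to high (mesenchymal arm). Half of each arm switches at the
  # epithelial->partial transition and half at the partial->mesenchymal one,
  # so partial-EMT cells co-express part of both programs -- the hybrid-state
  # structure the E/M score is designed to resolve. Crossing points sit
  # inside the latent gaps between class bands.
  lo <- 0.2; hi <- 1.8; slope <- 0.04
  two_waves <- function(n) {
    n_early <- ceiling(n / 2)
    c(stats::runif(n_early, 0.26, 0.34),
      stats::runif(n - n_early, 0.66, 0.74))
  }
  epi_cross <- two_waves(n_epi_genes)
  mes_cross <- two_waves(n_mes_genes)
  w_epi <- vapply(epi_cross, function(c0)
    lo + (hi - lo) * stats::plogis((c0 - latent) / slope), numeric(n_cells))
  w_mes <- vapply(mes_cross, function(c0)
    lo + (hi - lo) * stats::plogis((latent - c0) / slope), numeric(n_cells))
  w_bg <- matrix(1, n_cells, n_background_genes)
  w <- cbind(w_epi, w_mes, w_bg)
  if (n_mito_genes > 0) {
    # constant-rate mito genes sized to the target share of the library
    per_mito <- mito_fraction / (1 - mito_fraction) *
      mean(rowSums(w)) / n_mito_genes
    w <- cbind(w, matrix(per_mito, n_cells, n_mito_genes))
  }
  colnames(w) <- genes

  depth <- stats::rlnorm(n_cells, meanlog = log(mean_depth) - 0.045,
                         sdlog = 0.3)
  mu <- w / rowSums(w) * depth
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = dispersion),
    nrow = n_cells)
  if (dropout_rate > 0) {
    keep <- matrix(stats::rbinom(length(mu), 1L, 1 - dropout_rate),
                   nrow = n_cells)
    counts <- counts * keep
  }
  dimnames(counts) <- list(sprintf("cell%05d", seq_len(n_cells)), genes)
  dimnames(mu) <- dimnames(counts)

  list(
    counts = emt_counts(counts, sample = sample_id,
                        mito = genes %in% mito_genes),
    signature = emt_signature(epi_genes, mes_genes, name = "synthetic"),
    truth = data.frame(cell_id = rownames(counts), latent_emt = latent,
                       true_class = true_class, sample_id = sample_id,
                       stringsAsFactors = FALSE),
    mu = mu
  )
}

#' Simulate histology composition tables
#'
#' Draws specimen compositions over the six histopathology categories
#' (normal, PanIN, well-/moderately-/poorly-differentiated PDAC, necrosis)
#' as normalized gamma variates (a Dirichlet draw) scaled to percentages, or
#' emits a fixed template composition for every specimen.
#'
#' @param n_specimens number of specimens (>= 1).
#' @param seed integer seed.
#' @param template optional named numeric of percentages summing to 100
#'   (names among the six categories; missing categories are 0), or the
#'   shorthand `"all-panin"` for `{PanIN: 100}`.
#' @param shape Dirichlet concentration per category (default favours
#'   PanIN/PDAC-dominated tumours with occasional necrosis).
#' @return Data frame with `specimen_id` and the six percentage columns
#'   `normal`, `panin`, `pdac_well`, `pdac_moderate`, `pdac_poor`,
#'   `necrosis`; each row sums to 100.
#' @export
simulate_histology <- function(n_specimens, seed = 1, template = NULL,
                               shape = c(normal = 2, panin = 3, pdac_well = 3,
                                         pdac_moderate = 3, pdac_poor = 1,
                                         necrosis = 0.7)) {
  if (n_specimens < 1) stop("n_specimens must be >= 1", call. = FALSE)
  cats <- c("normal", "panin", "pdac_well", "pdac_moderate", "pdac_poor",
            "necrosis")
  set.seed(as.integer(seed))
  if (!is.null(template)) {
    if (identical(template, "all-panin")) template <- c(panin = 100)
    row <- stats::setNames(numeric(6), cats)
    bad <- setdiff(names(template), cats)
    if (length(bad) > 0)
      stop("unknown histology categories: ", paste(bad, collapse = ", "),
           call. = FALSE)
    row[names(template)] <- template
    if (abs(sum(row) - 100) > 1e-9)
      stop("template percentages must sum to 100", call. = FALSE)
    out <- as.data.frame(matrix(rep(row, each = n_specimens), n_specimens, 6,
                                dimnames = list(NULL, cats)))
  } else {
    g <- matrix(stats::rgamma(n_specimens * 6, shape = rep(shape[cats],
                                                           each = n_specimens)),
                n_specimens, 6, dimnames = list(NULL, cats))
    out <- as.data.frame(g / rowSums(g) * 100)
  }
  cbind(specimen_id = sprintf("spec%03d", seq_len(n_specimens)), out)
}

#' Simulate a marked point pattern of cancer cells and T cells
#'
#' Places `n_cancer` cancer cells and `n_tcell` T cells in a rectangular
#' window (micrometres) under one of three interaction regimes:
#' \describe{
#'   \item{csr}{both phenotypes independent and uniform (complete spatial
#'     randomness).}
#'   \item{attraction}{T cells are offset from randomly chosen cancer
#'     "parents" by isotropic Gaussian displacements of scale
#'     `interaction_scale` (Thomas-process style clustering around cancer
#'     cells).}
#'   \item{exclusion}{uniform T-cell candidates falling within
#'     `interaction_scale` of any cancer cell are rejected and redrawn
#'     (hard-core avoidance).}
#' }
#'
#' @param n_cancer,n_tcell point counts (>= 1).
#' @param window numeric `c(xmin, xmax, ymin, ymax)` in micrometres.
#' @param interaction one of `"csr"`, `"attraction"`, `"exclusion"`.
#' @param interaction_scale interaction length scale in micrometres.
#' @param seed integer seed.
#' @param max_tries rejection budget per T cell under `"exclusion"`; an
#'   infeasible density fails explicitly rather than looping forever.
#' @return A [point_pattern] with phenotype marks `"cancer"` and `"tcell"`.
#' @export
simulate_point_pattern <- function(n_cancer, n_tcell,
                                   window = c(0, 1000, 0, 1000),
                                   interaction = c("csr", "attraction",
                                                   "exclusion"),
                                   interaction_scale = 20,
                                   seed = 1,
                                   max_tries = 1000L) {
  interaction <- match.arg(interaction)
  if (n_cancer < 1 || n_tcell < 1) stop("point counts must be >= 1",
                                        call. = FALSE)
  window <- as.numeric(window)
  if (length(window) != 4L || window[2] <= window[1] || window[4] <= window[3])
    stop("window must be c(xmin, xmax, ymin, ymax) with positive area",
         call. = FALSE)
  set.seed(as.integer(seed))
  runif_win <- function(n) cbind(
    stats::runif(n, window[1], window[2]),
    stats::runif(n, window[3], window[4]))
  cancer <- runif_win(n_cancer)
  if (interaction == "csr") {
    tcell <- runif_win(n_tcell)
  } else if (interaction == "attraction") {
    tcell <- matrix(NA_real_, n_tcell, 2)
    for (i in seq_len(n_tcell)) {
      repeat {
        parent <- cancer[sample.int(n_cancer, 1L), ]
        p <- parent + stats::rnorm(2, sd = interaction_scale)
        if (p[1] >= window[1] && p[1] <= window[2] &&
            p[2] >= window[3] && p[2] <= window[4]) {
          tcell[i, ] <- p
          break
        }
      }
    }
  } else {
    tcell <- matrix(NA_real_, n_tcell, 2)
    for (i in seq_len(n_tcell)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        p <- runif_win(1L)
        d2 <- (cancer[, 1] - p[1])^2 + (cancer[, 2] - p[2])^2
        if (min(d2) >= interaction_scale^2) {
          tcell[i, ] <- p
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("exclusion sampling failed: window too crowded for ",
             "interaction_scale = ", interaction_scale, call. = FALSE)
    }
  }
  point_pattern(
    x = c(cancer[, 1], tcell[, 1]),
    y = c(cancer[, 2], tcell[, 2]),
    phenotype = rep(c("cancer", "tcell"), c(n_cancer, n_tcell)),
    window = window
  )
}
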