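# Small fixtures built in code; sizes chosen so the suite stays fast.

small_population <- function(n_cells = 300, seed = 1, ...) {
  # background kept at the default 400 genes so cells clear the QC
  # detected-gene floor; the signature arms are halved for speed
  simulate_emt_population(n_cells = n_cells, n_epi_genes = 30,
                          n_mes_genes = 30,
                          n_mito_genes = 5, seed = seed, ...)
}

# cells x genes matrix with named dimensions from a plain numeric matrix
named_matrix <- function(m) {
  rownames(m) <- paste0("c", seq_len(nrow(m)))
  colnames(m) <- paste0("g", seq_len(ncol(m)))
  m
}

# three well-separated Gaussian blobs in `g` dimensions
blob_matrix <- function(n_per = 30, g = 10, sep = 20, n_blobs = 3, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(n_blobs * g), n_blobs, g) * sep
  x <- do.call(rbind, lapply(seq_len(n_blobs), function(b)
    sweep(matrix(stats::rnorm(n_per * g), n_per, g), 2, centers[b, ], "+")))
  named_matrix(x)
}

# brute-force bivariate K: direct double loop over cross pairs
brute_force_k <- function(pattern, from_mark, to_mark, radii) {
  p <- pattern$points
  from <- p[p$phenotype == from_mark, ]
  to <- p[p$phenotype == to_mark, ]
  w <- pattern$window
  area <- (w[2] - w[1]) * (w[4] - w[3])
  vapply(radii, function(r) {
    total <- 0
    for (i in seq_len(nrow(from))) {
      for (j in seq_len(nrow(to))) {
        d <- sqrt((from$x_um[i] - to$x_um[j])^2 +
                  (from$y_um[i] - to$y_um[j])^2)
        if (d <= r) total <- total + 1
      }
    }
    area / (nrow(from) * nrow(to)) * total
  }, numeric(1))
}

# brute-force kNN-kernel affinity: all-pairs computation restricted to the
# kNN support, mirroring the documented kernel definition
brute_force_affinity <- function(x, k, decay) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    nn <- ord[seq_len(k)]
    sigma <- d[i, nn[k]]
    if (sigma == 0) sigma <- min(d[i, ][d[i, ] > 0])
    for (j in nn) a[i, j] <- exp(-(d[i, j] / sigma)^decay)
    a[i, i] <- 1
  }
  (a + t(a)) / 2
}
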