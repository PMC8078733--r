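test_that("point pattern construction and CSV IO validate coordinates", {
  p <- point_pattern(c(1, 2), c(3, 4), c("cancer", "tcell"),
                     window = c(0, 10, 0, 10))
  expect_s3_class(p, "point_pattern")
  expect_error(point_pattern(11, 5, "cancer", c(0, 10, 0, 10)), "inside")
  expect_error(point_pattern(1, 1, "cancer", c(0, 0, 0, 10)), "positive area")

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_point_pattern(p, tmp)
  back <- read_point_pattern(tmp, window = c(0, 10, 0, 10))
  expect_equal(back$points, p$points)

  # unlabelled coordinate columns are rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,phenotype", "1,2,cancer"), bad)
  expect_error(read_point_pattern(bad), "x_um")
})

test_that("bivariate K matches its closed form on a single pair", {
  # one cancer and one T cell at distance 5 in a 100 x 100 window:
  # K jumps from 0 to |W| at r = 5
  p <- point_pattern(c(10, 15), c(10, 10), c("cancer", "tcell"),
                     window = c(0, 100, 0, 100))
  k <- bivariate_k(p, "cancer", "tcell", radii = c(1, 4.99, 5, 10))
  expect_equal(k, c(0, 0, 1e4, 1e4))
})

test_that("K is non-decreasing, mark-symmetric and matches brute force", {
  p <- simulate_point_pattern(50, 50, window = c(0, 500, 0, 500), seed = 4)
  radii <- seq(5, 100, by = 5)
  k <- bivariate_k(p, "cancer", "tcell", radii)
  expect_true(all(diff(k) >= 0))
  # symmetry in marks without edge correction
  k_rev <- bivariate_k(p, "tcell", "cancer", radii)
  expect_equal(k, k_rev, tolerance = 1e-10)
  # brute-force double loop agreement
  kb <- brute_force_k(p, "cancer", "tcell", radii)
  expect_equal(k, kb, tolerance = 1e-10)

  expect_error(bivariate_k(p, "cancer", "tcell", radii = 300), "half")
  expect_error(bivariate_k(p, "cancer", "stroma", radii = 10), "stroma")
})

test_that("L transform has its closed-form values", {
  r <- seq(0.5, 10, by = 0.5)
  expect_equal(l_from_k(pi * r^2), r)
  expect_equal(l_from_k(0), 0)
  expect_equal(l_from_k(4 * pi), 2)
  expect_error(l_from_k(-1), "non-negative")
})

test_that("translation correction removes the edge-effect bias direction", {
  p <- simulate_point_pattern(80, 80, window = c(0, 200, 0, 200), seed = 5)
  radii <- seq(5, 50, by = 5)
  k_none <- bivariate_k(p, "cancer", "tcell", radii)
  k_tr <- bivariate_k(p, "cancer", "tcell", radii,
                      edge_correction = "translation")
  # translation weights are >= 1, so corrected K dominates uncorrected
  expect_true(all(k_tr >= k_none))
})

test_that("L AUC integrates the curve and scales equivariantly", {
  p <- simulate_point_pattern(60, 60, seed = 6)
  lc <- l_auc(p, r_max = 20, n_radii = 40)
  # the AUC equals the trapezoidal integral of the curve
  tr <- sum(diff(lc$radii) * (head(lc$l_values, -1) +
                              tail(lc$l_values, -1)) / 2)
  expect_equal(lc$auc, tr)
  expect_true(all(diff(lc$radii) > 0) && all(lc$radii > 0))

  # scaling coordinates and window by c scales L(r) to c * L(r / c)
  c0 <- 3
  ps <- point_pattern(p$points$x_um * c0, p$points$y_um * c0,
                      p$points$phenotype, p$window * c0)
  r <- seq(2, 20, by = 2)
  l1 <- l_from_k(bivariate_k(p, "cancer", "tcell", r))
  l2 <- l_from_k(bivariate_k(ps, "cancer", "tcell", r * c0))
  expect_equal(l2, c0 * l1, tolerance = 1e-10)
})

test_that("under CSR the mean of K(r) - pi r^2 is within Monte-Carlo error of 0", {
  # calibration is checked on the K scale: L = sqrt(K/pi) is concave, so
  # mean L sits below r wherever K is mostly zero (Jensen), even for an
  # unbiased K estimator
  n_sim <- 100
  r <- seq(0.5, 20, length.out = 40)
  dev <- t(vapply(seq_len(n_sim), function(s) {
    p <- simulate_point_pattern(50, 50, window = c(0, 1000, 0, 1000),
                                seed = s)
    bivariate_k(p, "cancer", "tcell", r) - pi * r^2
  }, numeric(length(r))))
  m <- colMeans(dev)
  se <- apply(dev, 2, stats::sd) / sqrt(n_sim)
  expect_true(all(abs(m) <= 3 * se))
})

test_that("AUC orders attraction > CSR > exclusion", {
  seeds <- 1:50
  auc_of <- function(interaction, s)
    l_auc(simulate_point_pattern(50, 50, window = c(0, 1000, 0, 1000),
                                 interaction = interaction,
                                 interaction_scale = 20, seed = s))$auc
  att <- vapply(seeds, function(s) auc_of("attraction", s), numeric(1))
  csr <- vapply(seeds, function(s) auc_of("csr", s), numeric(1))
  exc <- vapply(seeds, function(s) auc_of("exclusion", s), numeric(1))
  expect_gt(mean(att), mean(csr))
  expect_gt(mean(csr), mean(exc))
})

test_that("contact counts match a brute-force double loop", {
  p <- simulate_point_pattern(30, 40, window = c(0, 300, 0, 300), seed = 7)
  cc <- contact_counts(p, "cancer", "tcell", radius = 25)
  pts <- p$points
  from <- pts[pts$phenotype == "cancer", ]
  to <- pts[pts$phenotype == "tcell", ]
  manual <- vapply(seq_len(nrow(from)), function(i)
    sum(sqrt((from$x_um[i] - to$x_um)^2 +
             (from$y_um[i] - to$y_um)^2) <= 25), numeric(1))
  expect_equal(cc$counts, as.integer(manual))
  expect_equal(cc$mean, mean(manual))
  expect_error(contact_counts(p, "cancer", "tcell", radius = 0), "positive")

  # a single pair closer than the radius counts once
  p2 <- point_pattern(c(0, 3), c(0, 4), c("cancer", "tcell"),
                      window = c(-10, 10, -10, 10))
  expect_equal(contact_counts(p2, "cancer", "tcell", 6)$counts, 1L)
})
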