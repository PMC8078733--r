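test_that("population generator is deterministic and validates input", {
  a <- small_population(n_cells = 100, seed = 7)
  b <- small_population(n_cells = 100, seed = 7)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  expect_error(simulate_emt_population(n_cells = 5), "at least 10")
  expect_error(small_population(mixture_weights = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(small_population(dropout_rate = 1), "dropout_rate")
})

test_that("degenerate mixture yields a single class", {
  pop <- small_population(n_cells = 50, seed = 2,
                          mixture_weights = c(1, 0, 0))
  expect_true(all(pop$truth$true_class == "EPI"))
  expect_true(all(pop$truth$latent_emt <= 0.25))
})

test_that("latent coordinates stay in class bands and [0, 1]", {
  pop <- small_population(n_cells = 400, seed = 5)
  tr <- pop$truth
  expect_true(all(tr$latent_emt >= 0 & tr$latent_emt <= 1))
  bands <- list(EPI = c(0, 0.25), PEMT = c(0.35, 0.65), MES = c(0.75, 1))
  for (cl in names(bands)) {
    v <- tr$latent_emt[tr$true_class == cl]
    expect_true(all(v >= bands[[cl]][1] & v <= bands[[cl]][2]))
  }
})

test_that("empirical class fractions match the mixture weights", {
  pop <- simulate_emt_population(n_cells = 3000, n_background_genes = 40,
                                 mixture_weights = c(0.4, 0.35, 0.25),
                                 seed = 1)
  frac <- table(factor(pop$truth$true_class, c("EPI", "PEMT", "MES"))) / 3000
  expect_true(all(abs(frac - c(0.4, 0.35, 0.25)) < 0.03))
})

test_that("signature arms are monotone along the latent axis (noise-free)", {
  pop <- small_population(n_cells = 200, seed = 4)
  epi_mean <- rowMeans(pop$mu[, pop$signature$epithelial_genes])
  mes_mean <- rowMeans(pop$mu[, pop$signature$mesenchymal_genes])
  lat <- pop$truth$latent_emt
  expect_lt(stats::cor(lat, epi_mean, method = "spearman"), 0)
  expect_gt(stats::cor(lat, mes_mean, method = "spearman"), 0)
})

test_that("mitochondrial genes carry the prefix and a controllable share", {
  pop <- small_population(n_cells = 200, seed = 6, mito_fraction = 0.08)
  mito <- pop$counts$mito
  expect_true(all(startsWith(colnames(pop$counts$counts)[mito], "MT-")))
  share <- sum(pop$counts$counts[, mito]) / sum(pop$counts$counts)
  expect_equal(share, 0.08, tolerance = 0.25)
})

test_that("count matrix round-trips through MTX + sidecars", {
  pop <- small_population(n_cells = 40, seed = 8)
  dir <- withr::local_tempdir()
  write_emt_counts(pop$counts, dir)
  back <- read_emt_counts(dir)
  expect_equal(back$counts, pop$counts$counts)
  expect_identical(back$sample, pop$counts$sample)
  expect_identical(back$mito, pop$counts$mito)
})

test_that("histology generator rows sum to 100 and honour templates", {
  h <- simulate_histology(20, seed = 3)
  cats <- c("normal", "panin", "pdac_well", "pdac_moderate", "pdac_poor",
            "necrosis")
  expect_equal(rowSums(h[, cats]), rep(100, 20), tolerance = 1e-9)
  expect_true(all(as.matrix(h[, cats]) >= 0))
  expect_identical(simulate_histology(5, seed = 1), simulate_histology(5, seed = 1))

  t1 <- simulate_histology(3, seed = 1, template = "all-panin")
  expect_equal(t1$panin, rep(100, 3))
  expect_equal(rowSums(t1[, setdiff(cats, "panin")]), rep(0, 3))
})

test_that("point-pattern generator respects seeds, windows and interactions", {
  p1 <- simulate_point_pattern(30, 30, seed = 5)
  p2 <- simulate_point_pattern(30, 30, seed = 5)
  expect_identical(p1$points, p2$points)
  w <- p1$window
  expect_true(all(p1$points$x_um >= w[1] & p1$points$x_um <= w[2]))
  expect_true(all(p1$points$y_um >= w[3] & p1$points$y_um <= w[4]))

  # exclusion guarantees a minimum cancer-T-cell distance
  pe <- simulate_point_pattern(50, 50, interaction = "exclusion",
                               interaction_scale = 20, seed = 2)
  cc <- contact_counts(pe, "cancer", "tcell", radius = 20)
  expect_true(all(cc$counts == 0))

  # infeasible exclusion density fails explicitly
  expect_error(
    simulate_point_pattern(500, 10, window = c(0, 100, 0, 100),
                           interaction = "exclusion",
                           interaction_scale = 30, seed = 1, max_tries = 50),
    "exclusion")
})

test_that("attraction enriches close cancer-T-cell pairs relative to CSR", {
  mean20 <- function(interaction, seed)
    contact_counts(simulate_point_pattern(40, 40, interaction = interaction,
                                          interaction_scale = 20,
                                          seed = seed),
                   "cancer", "tcell", radius = 20)$mean
  seeds <- 1:50
  att <- vapply(seeds, function(s) mean20("attraction", s), numeric(1))
  csr <- vapply(seeds, function(s) mean20("csr", s), numeric(1))
  expect_gt(mean(att), mean(csr))
})
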