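test_that("positive_fraction counts strictly positive scaled entries", {
  m <- named_matrix(matrix(c(1, -1, 2, 3), 2, 2))
  expect_equal(positive_fraction(m, 1:2, 1:2), 0.75)
  expect_equal(positive_fraction(abs(m), 1:2, 1:2), 1)
  expect_error(positive_fraction(m, integer(0), 1:2), "empty cell")
  expect_error(positive_fraction(m, 1:2, integer(0)), "empty gene")
  # zero entries are not positive
  expect_equal(positive_fraction(matrix(0, 2, 2), 1:2, 1:2), 0)
  # symmetric values approach one half
  set.seed(1)
  big <- matrix(rnorm(1e4), 100)
  expect_equal(positive_fraction(big, 1:100, 1:100), 0.5, tolerance = 0.02)
})

test_that("em_score computes Log2(EPI/MES) with inclusive boundaries", {
  expect_equal(em_score(0.4, 0.4)$score, 0)
  expect_equal(as.character(em_score(0.4, 0.4)$em_class), "PEMT")
  expect_equal(em_score(0.8, 0.1)$score, 3, tolerance = 1e-4)
  expect_equal(as.character(em_score(0.8, 0.1)$em_class), "EPI")
  # boundaries: a score of exactly 1.5 is epithelial, exactly -1.5
  # mesenchymal, strictly in between partial-EMT
  expect_equal(as.character(classify_em_score(c(1.5, -1.5, 1.499, -1.499))),
               c("EPI", "MES", "PEMT", "PEMT"))
  expect_error(em_score(1.2, 0.5), "\\[0, 1\\]")
  # pseudocount guards zero fractions
  expect_true(is.finite(em_score(0.5, 0)$score))
})

test_that("em_score is antisymmetric and monotone", {
  set.seed(2)
  a <- runif(50); b <- runif(50)
  cuts <- phenotype_cutoffs(pseudocount = 1e-12)
  expect_equal(em_score(a, b, cuts)$score, -em_score(b, a, cuts)$score,
               tolerance = 1e-6)
  # increasing EPI at fixed MES strictly increases the score
  eps <- sort(runif(20))
  s <- em_score(eps, rep(0.3, 20))$score
  expect_true(all(diff(s) > 0))
})

test_that("cluster scoring, ordering and tie-breaks behave as stated", {
  # three blocks of cells with known positive patterns
  x <- named_matrix(rbind(
    matrix(1, 4, 4),                             # all positive
    matrix(c(1, 1, -1, -1), 4, 4, byrow = TRUE), # epi positive only
    matrix(c(-1, -1, 1, 1), 2, 4, byrow = TRUE))) # mes positive only
  colnames(x) <- c("E1", "E2", "M1", "M2")
  sig <- emt_signature(c("E1", "E2"), c("M1", "M2"))
  cl <- rep(c(2L, 1L, 3L), c(4L, 4L, 2L))
  tab <- score_clusters(x, cl, sig)
  expect_equal(tab$epi_fraction[tab$cluster == 1], 1)
  expect_equal(tab$mes_fraction[tab$cluster == 1], 0)
  expect_equal(tab$epi_fraction[tab$cluster == 2], 1)
  expect_equal(tab$mes_fraction[tab$cluster == 2], 1)

  ord <- order_clusters(tab, cl)
  # most epithelial first: old cluster 1 (epi only) -> new 1,
  # old 2 (all positive, score 0) -> new 2, old 3 (mes only) -> new 3
  expect_equal(ord$table$cluster, 1:3)
  expect_true(all(diff(ord$table$score) < 0))
  expect_equal(unname(ord$assignment[1:4]), rep(2L, 4))
  expect_equal(unname(ord$assignment[5:8]), rep(1L, 4))

  # idempotence on a sorted table
  again <- order_clusters(ord$table)
  expect_equal(again$table, ord$table)

  # tie on score: larger cluster first
  tied <- tab
  tied$score <- c(1, 1, 0)
  tied$n_cells <- c(2L, 6L, 2L)
  t2 <- order_clusters(tied)$table
  expect_equal(t2$n_cells[1:2], c(6L, 2L))
})

test_that("phenotype proportions are cell-weighted and sum to 100", {
  tab <- data.frame(cluster = 1:3,
                    em_class = factor(c("EPI", "PEMT", "MES"),
                                      c("EPI", "PEMT", "MES")))
  cl <- c(1L, 1L, 2L, 3L)
  p <- phenotype_proportions(cl, tab)
  expect_equal(unname(p), c(50, 25, 25))
  expect_equal(sum(p), 100, tolerance = 1e-9)

  # single-class assignment
  p2 <- phenotype_proportions(rep(1L, 5), tab)
  expect_equal(unname(p2), c(100, 0, 0))

  # grouped output carries per-group rows plus overall
  g <- c("a", "a", "b", "b")
  m <- phenotype_proportions(cl, tab, group_by = g)
  expect_equal(rownames(m), c("a", "b", "overall"))
  expect_equal(unname(m["a", ]), c(100, 0, 0))
  expect_equal(unname(rowSums(m)), rep(100, 3), tolerance = 1e-9)
})

test_that("sample classification agrees between rules on pure samples", {
  x <- named_matrix(rbind(matrix(c(1, 1, -1, -1), 6, 4, byrow = TRUE),
                          matrix(c(-1, -1, 1, 1), 6, 4, byrow = TRUE)))
  colnames(x) <- c("E1", "E2", "M1", "M2")
  sig <- emt_signature(c("E1", "E2"), c("M1", "M2"))
  sample <- rep(c("A", "B"), each = 6)
  cl <- rep(c(1L, 2L), each = 6)
  tab <- score_clusters(x, cl, sig)

  pooled <- classify_samples(x, sig, sample)
  expect_equal(as.character(pooled$em_class), c("EPI", "MES"))
  plur <- classify_samples(x, sig, sample, assignment = cl, table = tab,
                           rule = "plurality")
  expect_equal(as.character(plur$em_class), c("EPI", "MES"))

  # balanced pooled fractions give PEMT
  xb <- named_matrix(matrix(c(1, -1, -1, 1), 4, 4, byrow = TRUE))
  colnames(xb) <- c("E1", "E2", "M1", "M2")
  bal <- classify_samples(xb, sig, rep("A", 4))
  expect_equal(as.character(bal$em_class), "PEMT")
})

test_that("samples drawn from single class bands are classified correctly", {
  w <- diag(3)[rep(1:3, length.out = 20), ]
  pop <- simulate_emt_population(n_cells = 600, n_epi_genes = 30,
                                 n_mes_genes = 30,
                                 n_mito_genes = 5, n_samples = 20,
                                 sample_weights = w, seed = 12)
  fit <- emt_spectrum(pop$counts, pop$signature, seed = 12)
  truth <- tapply(pop$truth$true_class, pop$truth$sample_id, function(v)
    unique(v))
  got <- as.character(fit$samples$em_class)
  names(got) <- fit$samples$sample_id
  expect_equal(got[names(truth)], unlist(truth), ignore_attr = TRUE)
})

test_that("scores and proportions are invariant to cell-order permutation", {
  pop <- small_population(n_cells = 200, seed = 13)
  fit1 <- emt_spectrum(pop$counts, pop$signature, seed = 13)
  set.seed(1)
  perm <- sample(nrow(pop$counts$counts))
  shuffled <- pop$counts[perm, ]
  fit2 <- emt_spectrum(shuffled, pop$signature, seed = 13)
  expect_equal(fit1$proportions["overall", ], fit2$proportions["overall", ],
               tolerance = 1e-9)
  expect_equal(sort(fit1$clusters$score), sort(fit2$clusters$score),
               tolerance = 1e-9)
})
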