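test_that("size factors follow median-of-ratios with unit geometric mean", {
  ids <- paste0("g", 1:20)
  set.seed(1)
  a <- rpois(20, 100) + 1
  m <- make_counts(c(a, a), ids, c("s1", "s2"))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  doubled <- make_counts(c(a, 2 * a), ids, c("s1", "s2"))
  expect_equal(unname(estimate_size_factors(doubled)),
               c(1 / sqrt(2), sqrt(2)))

  single <- make_counts(a, ids, "s1")
  expect_equal(unname(estimate_size_factors(single)), 1)

  sf <- estimate_size_factors(make_counts(rpois(60, 40) + 1, ids,
                                          c("s1", "s2", "s3")))
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-6)

  disjoint <- make_counts(c(1, 0, 0, 1), c("g1", "g2"), c("s1", "s2"))
  expect_error(estimate_size_factors(disjoint), "size factors")
})

test_that("identical conditions give zero fold change and p-value one", {
  ids <- paste0("g", 1:30)
  set.seed(2)
  a <- make_counts(rpois(90, 80) + 1, ids, paste0("a", 1:3))
  res <- suppressMessages(nb_wald_test(a, a))
  expect_equal(res$log2_fold_change, rep(0, nrow(res)))
  expect_equal(res$p_value, rep(1, nrow(res)))
})

test_that("result table satisfies its own Wald/p-value identities", {
  sim <- simulate_paired_counts(n_genes = 200, dispersion = 0.1,
                                class_fractions = c(unchanged = 0.8, II = 0.2),
                                seed = 5)
  res <- nb_wald_test(sim$transcriptome[, 1:3], sim$transcriptome[, 4:6])
  expect_equal(res$wald_statistic,
               res$log2_fold_change / res$standard_error, tolerance = 1e-8)
  expect_equal(res$p_value, 2 * pnorm(-abs(res$wald_statistic)),
               tolerance = 1e-8)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("swapping condition labels negates fold changes, keeps p-values", {
  sim <- simulate_paired_counts(n_genes = 150, dispersion = 0.1, seed = 8)
  a <- sim$transcriptome[, 1:3]; b <- sim$transcriptome[, 4:6]
  r1 <- nb_wald_test(a, b)
  r2 <- nb_wald_test(b, a)
  expect_equal(r1$log2_fold_change, -r2$log2_fold_change, tolerance = 1e-8)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
})

test_that("rescaling one library is absorbed by normalization", {
  sim <- simulate_paired_counts(n_genes = 300, dispersion = 0.1, seed = 9)
  a <- sim$transcriptome[, 1:3]; b <- sim$transcriptome[, 4:6]
  r1 <- nb_wald_test(a, b)
  a2 <- a; a2[, 1] <- a2[, 1] * 4
  r2 <- nb_wald_test(a2, b)
  expect_equal(r1$log2_fold_change, r2$log2_fold_change, tolerance = 0.05)
  expect_gt(cor(r1$wald_statistic, r2$wald_statistic), 0.99)
})

test_that("Wald statistics match an independent likelihood-fit oracle", {
  set.seed(13)
  ids <- paste0("g", 1:20)
  mu <- runif(20, 20, 500)
  alpha <- 0.08
  a <- make_counts(rnbinom(60, mu = rep(mu, 3), size = 1 / alpha),
                   ids, paste0("a", 1:3))
  b <- make_counts(rnbinom(60, mu = rep(mu * 2, 3), size = 1 / alpha),
                   ids, paste0("b", 1:3))
  keep <- rowSums(a) > 0 & rowSums(b) > 0
  a <- a[keep, ]; b <- b[keep, ]
  res <- nb_wald_test(a, b, dispersion = alpha)
  sf <- estimate_size_factors(cbind(a, b))
  for (g in seq_len(nrow(a))) {
    orc <- oracle_nb_wald(a[g, ], b[g, ], sf[1:3], sf[4:6], alpha)
    expect_equal(res$wald_statistic[g], unname(orc["stat"]),
                 tolerance = 1e-3)
  }
})

test_that("a planted 4-fold shift is recovered in the median fold change", {
  sim <- simulate_paired_counts(n_genes = 800, dispersion = 0.05,
                                class_fractions = c(unchanged = 0.9, II = 0.1),
                                lfc = 2, seed = 12)
  res <- nb_wald_test(sim$transcriptome[, 1:3], sim$transcriptome[, 4:6])
  planted <- sim$truth$gene_id[sim$truth$class == "II"]
  med <- median(res$log2_fold_change[res$gene_id %in% planted])
  expect_lt(abs(med - 2), 0.2)
})

test_that("DEG calls use strict double thresholds", {
  de <- make_de(c("g1", "g2", "g3", "g4"),
                lfc = c(1.5, 1.0, 3.0, -2.0),
                p = c(0.04, 0.04, 0.06, 0.01))
  degs <- call_degs(de)
  expect_identical(degs$up, "g1")
  expect_identical(degs$down, "g4")
  expect_false("g2" %in% c(degs$up, degs$down))  # log2FC exactly 1
  expect_false("g3" %in% c(degs$up, degs$down))  # p above threshold
})

test_that("TPM prefilter and all-zero rows drop genes from the output", {
  ids <- c("hi", "lo", "zero")
  ann <- make_annotation(ids, 1000)
  a <- make_counts(c(500, 1, 0, 600, 1, 0), ids, c("a1", "a2"))
  b <- make_counts(c(800, 1, 0, 700, 1, 0), ids, c("b1", "b2"))
  res <- suppressWarnings(suppressMessages(
    nb_wald_test(a, b, annotation = ann, tpm_filter = 10000)))
  expect_identical(res$gene_id, "hi")
})
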