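te_fixture <- function(tx, tl, ids = paste0("g", seq_along(tx))) {
  compute_te(make_counts(tx, ids, "s1"), make_counts(tl, ids, "s1"),
             "GV", "GV")
}

test_that("TE is the translatome/transcriptome TPM ratio above the filter", {
  te <- te_fixture(c(10, 7, 0.5), c(20, 7, 30))
  expect_equal(te$te[te$gene_id == "g1"], 2)
  expect_equal(te$log2_te[te$gene_id == "g1"], 1)
  expect_equal(te$te[te$gene_id == "g2"], 1)
  expect_equal(te$log2_te[te$gene_id == "g2"], 0)
  # transcriptome TPM below the filter: gene absent
  expect_false("g3" %in% te$gene_id)
})

test_that("TE is scale-free and log2_te consistent with te", {
  set.seed(3)
  tx <- matrix(rlnorm(40, 3), 10, 4,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  tl <- matrix(rlnorm(40, 3), 10, 4, dimnames = dimnames(tx))
  cond <- c("GV", "GV", "MII", "MII")
  te1 <- compute_te(tx, tl, cond, cond)
  # scaling both layers by 7 (and the filter accordingly) keeps TE fixed
  te2 <- compute_te(tx * 7, tl * 7, cond, cond, min_tpm = 7)
  expect_identical(te1$gene_id, te2$gene_id)
  expect_equal(te1$te, te2$te)
  expect_equal(te1$log2_te, log2(te1$te), tolerance = 1e-9)
  expect_equal(te1$te, te1$tpm_translatome / te1$tpm_transcriptome,
               tolerance = 1e-12)
})

test_that("mismatched gene sets or replicate structures are errors", {
  tx <- make_counts(c(5, 5), c("g1", "g2"), "s1")
  tl <- make_counts(c(5, 5), c("g1", "gX"), "s1")
  expect_error(compute_te(tx, tl, "GV", "GV"), "same genes")
  tl2 <- make_counts(c(5, 5, 5, 5), c("g1", "g2"), c("s1", "s2"))
  expect_error(compute_te(tx, tl2, "GV", c("GV", "GV")), "replicate")
})

test_that("high-TE selection is strict and threshold-monotone", {
  prof <- data.frame(gene_id = c("a", "b", "c"), condition = "MII",
                     log2_te = c(0.5, 1.0, 1.2))
  expect_identical(high_te_genes(prof, "MII", 1), "c")
  expect_length(high_te_genes(prof, "MII", -Inf), 3)
  expect_true(all(high_te_genes(prof, "MII", 2) %in%
                  high_te_genes(prof, "MII", 1)))
})

test_that("planted high-TE genes are recovered from simulated counts", {
  sim <- simulate_paired_counts(n_genes = 1000, dispersion = 0.05,
                                class_fractions = c(unchanged = 0.9, I = 0.1),
                                lfc = 2, depth = 1e6, seed = 21)
  ann <- sim$annotation
  tpm_tx <- counts_to_tpm(sim$transcriptome, ann)
  tpm_tl <- counts_to_tpm(sim$translatome, ann)
  te <- compute_te(tpm_tx, tpm_tl, sim$conditions, sim$conditions)
  high <- high_te_genes(te, "B", 1)
  planted <- sim$truth$gene_id[sim$truth$class == "I"]  # true TE 4 in B
  expect_gte(sum(planted %in% high), 0.9 * length(planted))
})

test_that("dual-omics classes follow the documented 3x3 grid", {
  tx <- make_de(c("g1", "g2", "g3"), lfc = c(0.2, -2, 0.1),
                p = c(0.4, 0.01, 0.9))
  tl <- make_de(c("g1", "g2", "g3"), lfc = c(2, -2, 0.3),
                p = c(0.001, 0.02, 0.5))
  cl <- classify_dual_omics(tx, tl)
  expect_identical(cl$class_label[cl$gene_id == "g1"], "I")
  expect_identical(cl$class_label[cl$gene_id == "g2"], "IV")
  expect_identical(cl$class_label[cl$gene_id == "g3"], "unchanged")
  # partition: every gene gets exactly one known label
  expect_false(anyNA(cl$class_label))
  expect_identical(anyDuplicated(cl$gene_id), 0L)
})

test_that("reversing the condition order mirrors the class grid", {
  tx <- make_de(c("g1", "g2"), lfc = c(0.2, 0.1), p = c(0.4, 0.9))
  tl <- make_de(c("g1", "g2"), lfc = c(2, 0.3), p = c(0.001, 0.5))
  fwd <- classify_dual_omics(tx, tl)
  tx$log2_fold_change <- -tx$log2_fold_change
  tl$log2_fold_change <- -tl$log2_fold_change
  rev <- classify_dual_omics(tx, tl)
  expect_identical(fwd$class_label[fwd$gene_id == "g1"], "I")
  expect_identical(rev$class_label[rev$gene_id == "g1"], "III")
  expect_identical(rev$class_label[rev$gene_id == "g2"], "unchanged")
})

test_that("a gene missing from one layer is treated as constant there", {
  tx <- make_de("g1", lfc = 0.1, p = 0.8)
  tl <- make_de(c("g1", "g2"), lfc = c(0.1, 3), p = c(0.8, 0.001))
  expect_message(cl <- classify_dual_omics(tx, tl), "one layer only")
  expect_identical(cl$class_label[cl$gene_id == "g2"], "I")
})

test_that("cross-species overlap counts follow set algebra", {
  expect_equal(cross_species_overlap(c("a", "b", "c"), c("b", "c", "d"))[1:3],
               list(a_only = 1, shared = 2, b_only = 1))
  expect_equal(cross_species_overlap(c("a", "b"), c("x", "y"))$shared, 0)
  sub <- cross_species_overlap(c("a", "b"), c("a", "b", "c", "d"))
  expect_equal(sub[1:3], list(a_only = 0, shared = 2, b_only = 2))
  expect_equal(sub$pct_shared_a, 100)
  map <- data.frame(a = c("a", "a"), b = c("A1", "A2"))
  expect_error(cross_species_overlap(c("a"), c("A1"), map), "one-to-one")
  map2 <- data.frame(a = c("a", "b"), b = c("A", "B"))
  ov <- cross_species_overlap(c("a", "b"), c("A", "Z"), map2)
  expect_equal(ov$shared, 1)
})
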