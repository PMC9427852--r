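test_that("PWM construction validates shape and renormalizes rows", {
  expect_error(pwm(matrix(0.25, 2, 3), "bad"), "4 columns")
  expect_error(pwm(matrix(0.25, 31, 4), "toolong"), "1..30")
  expect_warning(p <- pwm(matrix(c(0.3, 0.3, 0.2, 0.1), 1, 4), "offsum"),
                 "renormalized")
  expect_equal(rowSums(p$probabilities), 1, ignore_attr = TRUE)
  # zero cells floored, rows still sum to one
  p2 <- pwm(matrix(c(1, 0, 0, 0), 1, 4), "zero")
  expect_true(all(p2$probabilities > 0))
  expect_equal(rowSums(p2$probabilities), 1, ignore_attr = TRUE)
})

test_that("MEME minimal files parse with ids, RBP grouping and background", {
  path <- system.file("extdata", "demo_motifs_synthetic.meme",
                      package = "translatomics")
  pwms <- read_meme_motifs(path)
  expect_length(pwms, 6)
  expect_setequal(unique(vapply(pwms, `[[`, "", "rbp_name")),
                  c("CPEB_demo", "PCBP_demo", "RBFOX_demo", "SRSF_demo",
                    "QKI_demo"))
  expect_equal(nrow(pwms$CPEB_demo_2$probabilities), 8)

  empty <- tempfile(fileext = ".meme")
  writeLines("MEME version 4", empty)
  expect_warning(e <- read_meme_motifs(empty), "no motifs")
  expect_length(e, 0)

  dup <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "",
               "MOTIF m1", "letter-probability matrix: alength= 4 w= 1",
               "0.25 0.25 0.25 0.25", "",
               "MOTIF m1", "letter-probability matrix: alength= 4 w= 1",
               "0.25 0.25 0.25 0.25"), dup)
  expect_error(read_meme_motifs(dup), "duplicate motif id 'm1'")

  trunc <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "",
               "MOTIF m2", "letter-probability matrix: alength= 4 w= 3",
               "0.25 0.25 0.25 0.25"), trunc)
  expect_error(read_meme_motifs(trunc), "m2")
})

test_that("single-letter PWM scores and p-values match enumeration logic", {
  p <- pwm(matrix(c(1, 0, 0, 0), 1, 4), "A1")
  hit <- scan_pwm(c(x = "A"), p, pvalue_threshold = 1.01)
  expect_equal(hit$raw_score, 2.0, tolerance = 0.01)
  expect_equal(hit$score_pvalue, 0.25)
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, 1L)
})

test_that("a uniform PWM scores zero everywhere", {
  p <- pwm(matrix(0.25, 3, 4), "unif")
  hits <- scan_pwm(c(x = "ACGUACGU"), p, pvalue_threshold = 1.01)
  expect_equal(hits$raw_score, rep(0, 6))
  expect_equal(hits$score_pvalue, rep(1, 6))
})

test_that("scanning skips N windows and short sequences", {
  p <- pwm(matrix(c(1, 0, 0, 0), 1, 4), "A1")
  expect_identical(nrow(scan_pwm(c(x = ""), p, pvalue_threshold = 1.01)), 0L)
  hits <- scan_pwm(c(x = "ANA"), p, pvalue_threshold = 1.01)
  expect_equal(hits$start, c(0L, 2L))
  p3 <- pwm(matrix(0.25, 5, 4), "w5")
  expect_identical(nrow(scan_pwm(c(x = "ACG"), p3, pvalue_threshold = 1.01)), 0L)
})

test_that("a planted consensus is found at its planted position", {
  p <- pwm(rbind(c(0.9, 0.04, 0.03, 0.03),
                 c(0.03, 0.9, 0.04, 0.03),
                 c(0.03, 0.03, 0.04, 0.9)), "ACU")
  set.seed(77)
  bg <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
              collapse = "")
  seq <- paste0(substr(bg, 1, 20), "ACT", substr(bg, 24, 50))
  hits <- scan_pwm(c(g = seq), p, pvalue_threshold = 0.05)
  expect_true(20 %in% hits$start)
  top <- hits[which.max(hits$raw_score), ]
  expect_equal(top$score_pvalue,
               oracle_enum_pvalue(p, top$raw_score), tolerance = 1e-9)
})

test_that("scanning is position-covariant under prefixing", {
  p <- random_pwm(4, "cov")
  s <- "ACGTTGCAAGTC"
  h0 <- scan_pwm(c(g = s), p, pvalue_threshold = 1.01)
  h1 <- scan_pwm(c(g = paste0("GGGGG", s)), p, pvalue_threshold = 1.01)
  shifted <- h1[h1$start >= 5, ]
  expect_equal(shifted$start, h0$start + 5L)
  expect_equal(shifted$raw_score, h0$raw_score)
})

test_that("DP score p-values equal exhaustive enumeration for L <= 8", {
  set.seed(101)
  for (L in c(1, 2, 3, 5, 8)) {
    p <- random_pwm(L, paste0("L", L))
    # probe at genuinely attained scores from random sequences
    seqs <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
            collapse = ""), "")
    names(seqs) <- paste0("s", 1:5)
    hits <- scan_pwm(seqs, p, pvalue_threshold = 1.01)
    probe <- unique(hits$raw_score)
    expect_equal(pwm_score_pvalue(p, probe),
                 oracle_enum_pvalue(p, probe), tolerance = 1e-6)
  }
})

test_that("min-max normalization hits its endpoints and filters strictly", {
  p <- pwm(rbind(c(0.91, 0.03, 0.03, 0.03),
                 c(0.03, 0.91, 0.03, 0.03)), "AC")
  hits <- scan_pwm(c(best = "AC", worst = "GG", mid = "AG"), p,
                   pvalue_threshold = 1.01)
  norm <- normalize_and_filter(hits, list(AC = p), 0)
  expect_equal(norm$normalized_score[norm$gene_id == "best"], 1.0)
  expect_equal(norm$normalized_score[norm$gene_id == "worst"], 0.0)
  expect_identical(nrow(norm), nrow(hits))  # threshold 0 keeps everything
  strict <- normalize_and_filter(hits, list(AC = p), 0.8)
  expect_identical(strict$gene_id, "best")
  # any positive threshold removes the minimal-score hit
  tiny <- normalize_and_filter(hits, list(AC = p), 1e-9)
  expect_false("worst" %in% tiny$gene_id)
})

test_that("degenerate PWMs are dropped at normalization with a warning", {
  p <- pwm(matrix(0.25, 2, 4), "flat")
  hits <- scan_pwm(c(x = "ACGT"), p, pvalue_threshold = 1.01)
  expect_warning(out <- normalize_and_filter(hits, list(flat = p), 0.5),
                 "degenerate")
  expect_identical(nrow(out), 0L)
})
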