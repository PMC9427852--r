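# Shared fixture builders and independent oracles.

make_annotation <- function(gene_ids, lengths = 1000,
                            biotype = "protein_coding") {
  data.frame(gene_id = gene_ids, gene_name = gene_ids,
             biotype = rep_len(biotype, length(gene_ids)),
             effective_length = rep_len(lengths, length(gene_ids)),
             stringsAsFactors = FALSE)
}

make_counts <- function(values, gene_ids, sample_ids) {
  matrix(values, nrow = length(gene_ids),
         dimnames = list(gene_ids, sample_ids))
}

# Minimal DE result table for classification tests.
make_de <- function(gene_ids, lfc, p) {
  data.frame(gene_id = gene_ids, base_mean = 100,
             log2_fold_change = lfc,
             standard_error = abs(lfc) / 2 + 0.1,
             wald_statistic = 0, p_value = p,
             stringsAsFactors = FALSE)
}

# Independent NB oracle: per-group log-mean MLE by 1-d optimize() on the
# dnbinom log-likelihood, expected Fisher information from the fitted
# means, Wald statistic on log2 scale. Used to cross-check the package's
# Newton fit.
oracle_nb_wald <- function(ka, kb, sf_a, sf_b, alpha) {
  fit_group <- function(k, sf) {
    nll <- function(eta) -sum(stats::dnbinom(k, mu = sf * exp(eta),
                                             size = 1 / alpha, log = TRUE))
    opt <- stats::optimize(nll, c(-30, 30), tol = 1e-12)
    eta <- opt$minimum
    mu <- sf * exp(eta)
    list(eta = eta, info = sum(mu / (1 + alpha * mu)))
  }
  fa <- fit_group(ka, sf_a)
  fb <- fit_group(kb, sf_b)
  lfc <- (fb$eta - fa$eta) / log(2)
  se <- sqrt(1 / fa$info + 1 / fb$info) / log(2)
  c(lfc = lfc, se = se, stat = lfc / se)
}

# Independent exhaustive oracle for PWM score p-values: enumerates all
# 4^L windows, scores each with its own (grid-rounded) arithmetic, and
# accumulates background probability mass at or above the queried score.
oracle_enum_pvalue <- function(pwm_obj, scores, background = rep(0.25, 4),
                               granularity = 1e-3) {
  p <- pwm_obj$probabilities
  L <- nrow(p)
  si <- round(log2(p / rep(background, each = L)) / granularity)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- Reduce(`+`, lapply(seq_len(L), function(j) si[j, grid[, j]]))
  pr <- Reduce(`*`, lapply(seq_len(L), function(j) background[grid[, j]]))
  vapply(scores, function(s)
    sum(pr[sc >= round(s / granularity)]), numeric(1))
}

random_pwm <- function(L, motif_id = "rnd") {
  m <- matrix(stats::runif(4 * L, 0.02, 1), L, 4)
  m <- m / rowSums(m)
  pwm(m, motif_id)
}
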