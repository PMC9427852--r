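#' Median-of-ratios size factors
#'
#' Library-size normalization for count matrices: each sample's factor is
#' the median across genes of the ratio of its count to the per-gene
#' geometric mean over samples (genes with a zero anywhere are excluded
#' from the reference). Factors are rescaled so their geometric mean is 1.
#'
#' @param counts Numeric count matrix, genes x samples.
#' @return Named numeric vector of strictly positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  assert_count_matrix(counts)
  if (ncol(counts) == 1) {
    sf <- 1
    names(sf) <- colnames(counts)
    return(sf)
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene expressed in all samples: size factors undefined")
  lc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- exp(apply(lc - ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

# NB log-mean MLE for one gene in one group, by Fisher scoring.
# counts: vector; sf: size factors; alpha: dispersion (var = mu + alpha mu^2).
# Returns list(q = fitted normalized mean, info = Fisher information of the
# log-mean). A zero group yields q = 0 with info computed at the pseudo
# floor supplied by the caller.
#' @noRd
nb_group_fit <- function(counts, sf, alpha, floor = 0.5) {
  qbar <- mean(counts / sf)
  if (qbar <= 0) {
    mu <- sf * floor
    return(list(q = 0, info = sum(mu / (1 + alpha * mu))))
  }
  eta <- log(qbar)
  for (it in 1:100) {
    mu <- sf * exp(eta)
    u <- sum((counts - mu) / (1 + alpha * mu))
    info <- sum(mu / (1 + alpha * mu))
    step <- u / info
    eta <- eta + step
    if (abs(step) < 1e-12) break
  }
  mu <- sf * exp(eta)
  list(q = exp(eta), info = sum(mu / (1 + alpha * mu)))
}

# Method-of-moments dispersion per gene from normalized counts, pooled
# within-condition variance; NA when no replication.
#' @noRd
mom_dispersion <- function(norm_a, norm_b) {
  na <- ncol(norm_a); nb <- ncol(norm_b)
  if (na < 2 && nb < 2) return(rep(NA_real_, nrow(norm_a)))
  ssq <- function(m) if (ncol(m) >= 2)
    rowSums((m - rowMeans(m))^2) else rep(0, nrow(m))
  df <- max(na - 1, 0) + max(nb - 1, 0)
  pooled_var <- (ssq(norm_a) + ssq(norm_b)) / df
  grand <- rowMeans(cbind(norm_a, norm_b))
  alpha <- (pooled_var - grand) / grand^2
  alpha[!is.finite(alpha)] <- NA_real_
  alpha
}

#' Negative-binomial Wald test between two conditions
#'
#' Per-gene two-group comparison under a negative-binomial model with
#' variance mu + alpha mu^2: median-of-ratios size factors estimated on
#' the combined matrix, method-of-moments gene-wise dispersions shrunk on
#' the log scale toward a log-log mean-dispersion trend, group log-means
#' fitted by Fisher scoring, and a Wald z statistic on the log2 fold
#' change with a two-sided normal p-value. Fold changes are condition B
#' over condition A (log2FC > 0 means higher in B).
#'
#' @param counts_a,counts_b Count matrices for the two conditions; same
#'   genes, same row order.
#' @param annotation Optional annotation (gene_id, effective_length); when
#'   supplied, genes are prefiltered to mean TPM strictly greater than
#'   `tpm_filter` across all samples before testing.
#' @param tpm_filter TPM prefilter threshold (default 1; strict `>`).
#' @param dispersion Optional known dispersion(s): scalar or per-gene
#'   vector. When supplied, estimation and shrinkage are skipped.
#' @param shrink_weight Weight of the fitted trend in the log-scale
#'   dispersion shrinkage, in [0, 1]. Default 0.7.
#' @param pseudo_floor Floor (normalized-count units) applied to a
#'   zero-mean condition when forming the fold change. Default 0.5.
#' @return data.frame with gene_id, base_mean, log2_fold_change,
#'   standard_error, wald_statistic, p_value. All-zero genes are dropped
#'   with a message.
#' @export
nb_wald_test <- function(counts_a, counts_b, annotation = NULL,
                         tpm_filter = 1, dispersion = NULL,
                         shrink_weight = 0.7, pseudo_floor = 0.5) {
  assert_count_matrix(counts_a, "counts_a")
  assert_count_matrix(counts_b, "counts_b")
  if (!identical(rownames(counts_a), rownames(counts_b)))
    stop("counts_a and counts_b must cover the same genes in the same order")
  if (ncol(counts_a) < 2 || ncol(counts_b) < 2)
    warning("fewer than 2 replicates in a condition: ",
            "dispersion is pooled across genes and power is limited")

  combined <- cbind(counts_a, counts_b)
  if (!is.null(annotation)) {
    tpm <- counts_to_tpm(combined, annotation)
    keep <- rowMeans(tpm) > tpm_filter
    counts_a <- counts_a[keep, , drop = FALSE]
    counts_b <- counts_b[keep, , drop = FALSE]
    combined <- combined[keep, , drop = FALSE]
    if (!is.null(dispersion) && length(dispersion) > 1)
      dispersion <- dispersion[keep]
  }
  nz <- rowSums(combined) > 0
  if (any(!nz)) {
    message("dropping ", sum(!nz), " all-zero gene(s)")
    counts_a <- counts_a[nz, , drop = FALSE]
    counts_b <- counts_b[nz, , drop = FALSE]
    combined <- combined[nz, , drop = FALSE]
    if (!is.null(dispersion) && length(dispersion) > 1)
      dispersion <- dispersion[nz]
  }
  ng <- nrow(combined)
  if (ng == 0) stop("no genes left to test")

  sf <- estimate_size_factors(combined)
  sf_a <- sf[seq_len(ncol(counts_a))]
  sf_b <- sf[ncol(counts_a) + seq_len(ncol(counts_b))]
  norm <- sweep(combined, 2, sf, "/")
  base_mean <- rowMeans(norm)

  if (is.null(dispersion)) {
    alpha <- estimate_dispersions(
      sweep(counts_a, 2, sf_a, "/"), sweep(counts_b, 2, sf_b, "/"),
      base_mean, shrink_weight)
  } else {
    alpha <- rep_len(dispersion, ng)
  }

  l2 <- log(2)
  lfc <- se <- numeric(ng)
  for (g in seq_len(ng)) {
    fa <- nb_group_fit(counts_a[g, ], sf_a, alpha[g], pseudo_floor)
    fb <- nb_group_fit(counts_b[g, ], sf_b, alpha[g], pseudo_floor)
    qa <- max(fa$q, pseudo_floor)
    qb <- max(fb$q, pseudo_floor)
    lfc[g] <- log2(qb / qa)
    se[g] <- sqrt(1 / fa$info + 1 / fb$info) / l2
  }
  stat <- lfc / se
  data.frame(
    gene_id = rownames(combined),
    base_mean = base_mean,
    log2_fold_change = lfc,
    standard_error = se,
    wald_statistic = stat,
    p_value = 2 * stats::pnorm(-abs(stat)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Gene-wise MoM dispersions shrunk toward a fitted mean-dispersion trend
# alpha(mu) = a0 + a1/mu, blended on the arithmetic scale (log-scale
# blending would bias the estimate low via the geometric mean). Without
# replication in both groups, falls back to a single pooled value from
# the across-all-samples moments.
#' @noRd
estimate_dispersions <- function(norm_a, norm_b, base_mean, shrink_weight) {
  ng <- length(base_mean)
  mom <- mom_dispersion(norm_a, norm_b)
  if (all(is.na(mom))) {
    all_norm <- cbind(norm_a, norm_b)
    v <- apply(all_norm, 1, stats::var)
    a <- (v - base_mean) / base_mean^2
    a <- a[is.finite(a) & a > 0]
    pooled <- if (length(a)) stats::median(a) else 0.1
    return(rep(max(pooled, 1e-8), ng))
  }
  mom_f <- pmax(mom, 1e-8)
  use <- !is.na(mom) & base_mean > 0
  if (sum(use) >= 10) {
    fit <- stats::lm(mom_f[use] ~ I(1 / base_mean[use]))
    cf <- stats::coef(fit)
    trend <- cf[1] + cf[2] / pmax(base_mean, 1e-8)
    trend <- pmax(trend, 1e-8)
  } else {
    trend <- rep(max(stats::median(mom_f[use]), 1e-8), ng)
  }
  alpha <- (1 - shrink_weight) * mom_f + shrink_weight * trend
  alpha[is.na(mom)] <- trend[is.na(mom)]
  pmax(alpha, 1e-8)
}

#' Call differentially expressed genes at fixed thresholds
#'
#' Up = p < p_threshold and log2FC > lfc_threshold; down = p < p_threshold
#' and log2FC < -lfc_threshold. Both inequalities strict.
#'
#' @param results data.frame from [nb_wald_test()].
#' @param p_threshold Raw p-value cutoff (default 0.05; no multiplicity
#'   adjustment, matching the thresholding convention this reproduces).
#' @param lfc_threshold log2 fold-change cutoff (default 1).
#' @return list(up = character vector, down = character vector).
#' @export
call_degs <- function(results, p_threshold = 0.05, lfc_threshold = 1) {
  stopifnot(p_threshold > 0, lfc_threshold > 0)
  sig <- results$p_value < p_threshold
  list(
    up = results$gene_id[sig & results$log2_fold_change > lfc_threshold],
    down = results$gene_id[sig & results$log2_fold_change < -lfc_threshold]
  )
}
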