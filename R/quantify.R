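#' Convert raw gene counts to TPM
#'
#' Transcripts per million from gene-level counts: per sample, each
#' gene's count is divided by its effective length (nt) and the
#' length-normalized rates are rescaled to sum to one million, so
#' `TPM_g = 1e6 * (count_g / len_g) / sum_j (count_j / len_j)`.
#'
#' @param counts Numeric matrix, genes x samples, gene ids as rownames.
#' @param annotation data.frame with at least gene_id and
#'   effective_length; must cover every counted gene.
#' @return Matrix of the same shape; every column sums to 1e6.
#' @examples
#' m <- matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' ann <- data.frame(gene_id = c("g1", "g2"), biotype = "protein_coding",
#'                   effective_length = c(1000, 2000))
#' counts_to_tpm(m, ann)  # both genes at 5e5
#' @export
counts_to_tpm <- function(counts, annotation) {
  assert_count_matrix(counts)
  ann <- annotation_for(counts, annotation)
  rate <- counts / ann$effective_length
  denom <- colSums(rate)
  zero <- denom <= 0
  if (any(zero))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero], collapse = ", "),
         " (TPM normalization undefined)")
  sweep(rate, 2, denom, "/") * 1e6
}

#' Restrict a matrix to protein-coding genes
#'
#' @param mat Count or TPM matrix with gene ids as rownames.
#' @param annotation Annotation data.frame covering all rows.
#' @return The matrix restricted to rows with biotype "protein_coding",
#'   original row order preserved. May have zero rows.
#' @export
filter_protein_coding <- function(mat, annotation) {
  ann <- annotation_for(mat, annotation)
  mat[ann$biotype == "protein_coding", , drop = FALSE]
}

#' Expressed-gene sets at a TPM threshold
#'
#' Genes whose TPM is strictly greater than `threshold` under the chosen
#' rule: in any sample, in all samples, or on the per-gene mean.
#'
#' @param tpm TPM matrix.
#' @param threshold Positive TPM cutoff (strict `>`); default 1.
#' @param rule One of "any_sample", "all_samples", "mean".
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(tpm, threshold = 1,
                            rule = c("any_sample", "all_samples", "mean")) {
  rule <- match.arg(rule)
  stopifnot(threshold > 0)
  if (nrow(tpm) == 0) return(character(0))
  keep <- switch(rule,
    any_sample  = apply(tpm > threshold, 1, any),
    all_samples = apply(tpm > threshold, 1, all),
    mean        = rowMeans(tpm) > threshold)
  rownames(tpm)[keep]
}

#' Pearson correlation between two expression profiles
#'
#' Used for the replicate / dilution-series concordance checks of paired
#' transcriptome and translatome libraries. By default the correlation is
#' computed on log2(TPM + 1).
#'
#' @param tpm_a,tpm_b Numeric vectors over the same genes, same order.
#' @param log_transform Correlate on log2(x + pseudocount)? Default TRUE.
#' @param pseudocount Added before the log; must be > 0. Default 1.
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
sample_correlation <- function(tpm_a, tpm_b, log_transform = TRUE,
                               pseudocount = 1) {
  if (length(tpm_a) != length(tpm_b))
    stop("profiles must cover the same genes in the same order")
  if (log_transform) {
    stopifnot(pseudocount > 0)
    tpm_a <- log2(tpm_a + pseudocount)
    tpm_b <- log2(tpm_b + pseudocount)
  }
  if (stats::sd(tpm_a) == 0 || stats::sd(tpm_b) == 0)
    stop("zero-variance profile: correlation undefined")
  stats::cor(tpm_a, tpm_b)
}
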