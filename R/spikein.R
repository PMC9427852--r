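#' Estimate non-specific capture from ERCC spike-ins
#'
#' Spike-in RNAs added to the lysate before ribosome affinity capture are
#' not translated, so any spike-in signal in the translatome library is
#' non-specific binding. The estimator is a ratio of library-composition
#' fractions: with `input_fraction` the spike-in read share of the
#' transcriptome library and `captured_fraction` the spike-in share of
#' the translatome library, the non-specific fraction is
#' `captured_fraction / input_fraction`. Both a per-sample estimate
#' (mean over paired columns) and a pooled estimate (fractions on summed
#' counts) are reported.
#'
#' @param transcriptome_counts,translatome_counts Count matrices with the
#'   same genes (endogenous + spike-ins) and paired sample columns in the
#'   same order.
#' @param spike_ids Character vector of spike-in row ids; must be present
#'   in both matrices.
#' @return list: per_sample (named vector of per-sample ratios),
#'   nonspecific_fraction (their mean), pooled (ratio on summed counts),
#'   input_fraction, captured_fraction (per-sample vectors).
#' @export
estimate_nonspecific_binding <- function(transcriptome_counts,
                                         translatome_counts, spike_ids) {
  assert_count_matrix(transcriptome_counts, "transcriptome_counts")
  assert_count_matrix(translatome_counts, "translatome_counts")
  if (ncol(transcriptome_counts) != ncol(translatome_counts))
    stop("layers must have the same (paired) sample columns")
  for (m in list(transcriptome_counts, translatome_counts)) {
    miss <- setdiff(spike_ids, rownames(m))
    if (length(miss))
      stop("spike-in id(s) absent from a count matrix: ",
           paste(utils::head(miss, 3), collapse = ", "))
  }
  frac <- function(m) {
    tot <- colSums(m)
    sp <- colSums(m[spike_ids, , drop = FALSE])
    if (any(tot == 0)) stop("a library has zero total counts")
    sp / tot
  }
  input_fraction <- frac(transcriptome_counts)
  captured_fraction <- frac(translatome_counts)
  if (any(input_fraction == 0))
    stop("zero spike-in reads in a transcriptome library: estimator undefined")
  per_sample <- captured_fraction / input_fraction
  pooled_in <- sum(transcriptome_counts[spike_ids, ]) / sum(transcriptome_counts)
  pooled_cap <- sum(translatome_counts[spike_ids, ]) / sum(translatome_counts)
  list(
    per_sample = per_sample,
    nonspecific_fraction = mean(per_sample),
    pooled = pooled_cap / pooled_in,
    input_fraction = input_fraction,
    captured_fraction = captured_fraction
  )
}
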