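# Occurrence counting and target-vs-background enrichment of RBP motif
# hits in 3'-UTRs.

#' Per-gene, per-RBP motif occurrence table
#'
#' Occurrence is the number of retained hits of any motif belonging to
#' the RBP within a gene's 3'-UTR, optionally per kilobase of UTR.
#'
#' @param hits Retained hit data.frame (after [normalize_and_filter()]).
#' @param genes Character vector of gene ids to tabulate (rows); genes
#'   with no hits get zeros.
#' @param per_kb Normalize by UTR length in kb? Default FALSE (raw
#'   counts; the occurrence statistic is unnormalized by default).
#' @param utr_lengths Named vector of UTR lengths (nt); required when
#'   `per_kb = TRUE`. Genes without a length are excluded with a message.
#' @return Numeric matrix, genes x RBPs.
#' @export
occurrence_table <- function(hits, genes, per_kb = FALSE,
                             utr_lengths = NULL) {
  genes <- unique(genes)
  if (per_kb) {
    if (is.null(utr_lengths)) stop("per_kb = TRUE requires utr_lengths")
    known <- genes %in% names(utr_lengths)
    if (!all(known)) {
      message("excluding ", sum(!known), " gene(s) without UTR length")
      genes <- genes[known]
    }
  }
  rbps <- sort(unique(hits$rbp_name))
  occ <- matrix(0, length(genes), length(rbps),
                dimnames = list(genes, rbps))
  sub <- hits[hits$gene_id %in% genes, , drop = FALSE]
  if (nrow(sub)) {
    tab <- table(factor(sub$gene_id, levels = genes),
                 factor(sub$rbp_name, levels = rbps))
    occ[] <- as.numeric(tab)
  }
  if (per_kb && length(genes))
    occ <- occ / (utr_lengths[genes] / 1000)
  occ
}

#' RBP motif enrichment in a target gene set
#'
#' For every RBP, compares per-gene motif occurrences between a target
#' and a background gene set with a one-sided Welch t-test (alternative:
#' target > background) and a log2 fold change of means with a small
#' pseudo-occurrence. The significance rule follows the strict raw-p
#' convention of this analysis family: log2FC > 1 and p < 1e-5, with no
#' multiple-testing correction (deliberate and documented).
#'
#' @param occurrences Matrix from [occurrence_table()] covering both sets.
#' @param target_genes,background_genes Disjoint gene-id vectors, each of
#'   length >= 2 and present in `occurrences`.
#' @param eps Pseudo-occurrence in the fold change (default 0.01).
#' @param lfc_threshold,p_threshold Significance thresholds (defaults 1
#'   and 1e-5, both strict).
#' @return data.frame: rbp_name, mean_occurrence_target,
#'   mean_occurrence_background, log2_fold_change, p_value, significant;
#'   ordered by p-value.
#' @export
motif_enrichment <- function(occurrences, target_genes, background_genes,
                             eps = 0.01, lfc_threshold = 1,
                             p_threshold = 1e-5) {
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  if (length(intersect(target_genes, background_genes)))
    stop("target and background gene sets must be disjoint")
  if (length(target_genes) < 2 || length(background_genes) < 2)
    stop("need >= 2 genes in each of target and background")
  miss <- setdiff(c(target_genes, background_genes), rownames(occurrences))
  if (length(miss))
    stop("genes absent from occurrence table: ", miss[1],
         if (length(miss) > 1) paste0(" (+", length(miss) - 1, " more)"))
  res <- lapply(colnames(occurrences), function(rbp) {
    x <- occurrences[target_genes, rbp]
    y <- occurrences[background_genes, rbp]
    mx <- mean(x); my <- mean(y)
    p <- if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mx > my) 0 else 1
    } else {
      stats::t.test(x, y, alternative = "greater")$p.value
    }
    data.frame(rbp_name = rbp,
               mean_occurrence_target = mx,
               mean_occurrence_background = my,
               log2_fold_change = log2((mx + eps) / (my + eps)),
               p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$log2_fold_change > lfc_threshold &
    out$p_value < p_threshold
  out <- out[order(out$p_value, -out$log2_fold_change), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upset-style co-occurrence counts of RBP target genes
#'
#' For every non-empty subset of `rbps`, counts the genes carrying at
#' least one retained hit for *each* RBP in the subset (superset-style
#' intersection counts, as in an upset plot of shared target genes).
#'
#' @param hits Retained hit data.frame.
#' @param rbps Character vector of RBP names (non-empty).
#' @param genes Gene universe to count within.
#' @return data.frame: subset (RBP names joined by "+"), size, n_genes;
#'   plus attribute "genes_all" with the ids carrying all RBPs' motifs.
#' @export
motif_co_occurrence <- function(hits, rbps, genes) {
  if (!length(rbps)) stop("rbps must be non-empty")
  genes <- unique(genes)
  targets <- lapply(rbps, function(r)
    intersect(genes, unique(hits$gene_id[hits$rbp_name == r])))
  names(targets) <- rbps
  out <- list()
  for (k in seq_along(rbps)) {
    combos <- utils::combn(rbps, k, simplify = FALSE)
    for (cc in combos) {
      shared <- Reduce(intersect, targets[cc])
      out[[length(out) + 1L]] <- data.frame(
        subset = paste(cc, collapse = "+"),
        size = k, n_genes = length(shared),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "genes_all") <- Reduce(intersect, targets)
  res
}
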