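#' Translation efficiency per gene and condition
#'
#' TE is the translatome TPM divided by the transcriptome TPM of the same
#' gene. Replicates are combined on the log scale: per condition the
#' reported TPM of each layer is the geometric mean over its replicates,
#' so TE equals the geometric mean of the per-replicate TPM ratios and
#' `log2_te` is the mean per-replicate log2 ratio. TE is reported only
#' for genes whose (geometric-mean) TPM exceeds `min_tpm` in *both*
#' layers of that condition; other genes are absent.
#'
#' @param tpm_transcriptome,tpm_translatome TPM matrices over identical
#'   gene sets (same rownames, same order).
#' @param conditions_transcriptome,conditions_translatome Condition label
#'   per column of the respective matrix. Each condition must have the
#'   same number of replicate columns in both layers.
#' @param min_tpm Expression filter (strict `>`), default 1.
#' @return data.frame: gene_id, condition, tpm_transcriptome,
#'   tpm_translatome, te, log2_te.
#' @export
compute_te <- function(tpm_transcriptome, tpm_translatome,
                       conditions_transcriptome, conditions_translatome,
                       min_tpm = 1) {
  stopifnot(min_tpm > 0)
  if (!identical(rownames(tpm_transcriptome), rownames(tpm_translatome)))
    stop("transcriptome and translatome matrices must cover the same genes ",
         "in the same order (no silent intersection)")
  if (length(conditions_transcriptome) != ncol(tpm_transcriptome) ||
      length(conditions_translatome) != ncol(tpm_translatome))
    stop("condition labels must match matrix columns")
  conds <- intersect(unique(conditions_transcriptome),
                     unique(conditions_translatome))
  if (!length(conds)) stop("no condition present in both layers")
  out <- lapply(conds, function(cond) {
    tx <- tpm_transcriptome[, conditions_transcriptome == cond, drop = FALSE]
    tl <- tpm_translatome[, conditions_translatome == cond, drop = FALSE]
    if (ncol(tx) != ncol(tl))
      stop("condition '", cond, "': unequal replicate numbers between layers")
    gm <- function(m) exp(rowMeans(log(m)))
    gtx <- gm(tx)
    gtl <- gm(tl)
    keep <- is.finite(gtx) & is.finite(gtl) & gtx > min_tpm & gtl > min_tpm
    te <- gtl[keep] / gtx[keep]
    data.frame(
      gene_id = rownames(tpm_transcriptome)[keep],
      condition = cond,
      tpm_transcriptome = gtx[keep],
      tpm_translatome = gtl[keep],
      te = te,
      log2_te = log2(te),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' High-TE gene set in one condition
#'
#' @param profiles data.frame from [compute_te()].
#' @param condition Condition to select.
#' @param log2_te_threshold Strict lower bound on log2 TE. The presets
#'   used in this analysis family are 0, 1 and 2 (TE > 1, 2, 4).
#' @return Character vector of gene ids.
#' @export
high_te_genes <- function(profiles, condition, log2_te_threshold = 1) {
  stopifnot(is.finite(log2_te_threshold) || log2_te_threshold == -Inf)
  sel <- profiles$condition == condition &
    profiles$log2_te > log2_te_threshold
  profiles$gene_id[sel]
}

.class_grid <- c(
  "constant.up"       = "I",
  "up.up"             = "II",
  "constant.down"     = "III",
  "down.down"         = "IV",
  "down.constant"     = "V",
  "up.constant"       = "VI",
  "up.down"           = "VII",
  "down.up"           = "VIII",
  "constant.constant" = "unchanged"
)

#' Dual-omics class assignment from paired DE results
#'
#' Each gene is called up / constant / down independently in the
#' transcriptome and translatome from the two Wald-test result tables
#' (same condition pair, same direction convention), using the standard
#' DEG thresholds. The pair of calls places the gene in a 3x3 grid of
#' eight informative classes plus "unchanged":
#' Class I = translationally up, transcriptionally constant;
#' Class IV = down in both layers (higher in the first condition);
#' the remaining cells follow the fixed package convention
#' II=(up,up), III=(constant,down), V=(down,constant), VI=(up,constant),
#' VII=(up,down), VIII=(down,up), written as (transcriptome, translatome).
#'
#' @param transcriptome_de,translatome_de data.frames from
#'   [nb_wald_test()] on the two layers.
#' @param p_threshold,lfc_threshold DEG thresholds passed to
#'   [call_degs()] (defaults 0.05 and 1, strict).
#' @return data.frame: gene_id, transcriptome_call, translatome_call,
#'   class_label. A gene present in only one layer's results is treated
#'   as constant in the missing layer (message emitted).
#' @export
classify_dual_omics <- function(transcriptome_de, translatome_de,
                                p_threshold = 0.05, lfc_threshold = 1) {
  call_layer <- function(de, genes) {
    degs <- call_degs(de, p_threshold, lfc_threshold)
    out <- rep("constant", length(genes))
    out[genes %in% degs$up] <- "up"
    out[genes %in% degs$down] <- "down"
    out
  }
  genes <- union(transcriptome_de$gene_id, translatome_de$gene_id)
  only_one <- sum(!genes %in% transcriptome_de$gene_id) +
    sum(!genes %in% translatome_de$gene_id)
  if (only_one > 0)
    message(only_one, " gene(s) present in one layer only; ",
            "missing layer treated as constant")
  tx <- call_layer(transcriptome_de, genes)
  tl <- call_layer(translatome_de, genes)
  data.frame(
    gene_id = genes,
    transcriptome_call = tx,
    translatome_call = tl,
    class_label = unname(.class_grid[paste(tx, tl, sep = ".")]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Cross-species overlap of two gene sets
#'
#' Counts how many genes of set A have their homolog in set B, for
#' Venn-style comparisons of, e.g., the translated gene sets of human and
#' mouse oocytes. Genes without a homolog mapping count as
#' species-specific.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param homolog_map data.frame with columns `a`, `b` (one-to-one on the
#'   genes considered), or NULL for identity mapping.
#' @return list: a_only, shared, b_only counts plus pct_shared_a /
#'   pct_shared_b, the shared percentage relative to each set.
#' @export
cross_species_overlap <- function(set_a, set_b, homolog_map = NULL) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (is.null(homolog_map)) {
    shared <- sum(set_a %in% set_b)
  } else {
    map <- homolog_map[homolog_map$a %in% set_a, , drop = FALSE]
    if (anyDuplicated(map$a) || anyDuplicated(map$b))
      stop("homolog map must be one-to-one on the genes considered")
    shared <- sum(map$b %in% set_b)
  }
  list(
    a_only = length(set_a) - shared,
    shared = shared,
    b_only = length(set_b) - shared,
    pct_shared_a = if (length(set_a)) 100 * shared / length(set_a) else NA_real_,
    pct_shared_b = if (length(set_b)) 100 * shared / length(set_b) else NA_real_
  )
}
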