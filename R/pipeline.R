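# End-to-end orchestration: quantify -> DE per layer -> dual-omics
# classes -> TE -> 3'-UTR motif enrichment -> CPE/PAS annotation, with a
# machine-readable JSON summary. All coordinates in outputs are 0-based,
# half-open.

#' Build a pipeline configuration
#'
#' @param counts_transcriptome,counts_translatome Paths to count TSVs
#'   (genes x samples).
#' @param sample_sheet Path to the sample sheet TSV (sample_id, layer,
#'   stage, ...). Stages select the two conditions compared.
#' @param annotation Path to the annotation TSV.
#' @param condition_a,condition_b Stage labels to compare (fold changes
#'   are B over A).
#' @param utr_fasta,motif_meme Optional paths enabling the 3'-UTR motif
#'   stage.
#' @param out_dir Output directory.
#' @param tpm_threshold,p_threshold,lfc_threshold,log2_te_threshold,
#'   motif_pvalue,normalized_score_min,cpe_window Stage thresholds
#'   (defaults 1, 0.05, 1, 1, 1e-4, 0.8, 100).
#' @param seed Integer seed for any stochastic step.
#' @return Named list of class `tnt_config`; unknown keys are rejected
#'   by [run_pipeline()].
#' @export
pipeline_config <- function(counts_transcriptome, counts_translatome,
                            sample_sheet, annotation,
                            condition_a, condition_b,
                            utr_fasta = NULL, motif_meme = NULL,
                            out_dir = tempfile("tnt_out"),
                            tpm_threshold = 1, p_threshold = 0.05,
                            lfc_threshold = 1, log2_te_threshold = 1,
                            motif_pvalue = 1e-4,
                            normalized_score_min = 0.8,
                            cpe_window = 100, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$tpm_threshold > 0, cfg$p_threshold > 0,
            cfg$p_threshold <= 1, cfg$lfc_threshold > 0,
            cfg$motif_pvalue > 0, cfg$motif_pvalue <= 1,
            cfg$normalized_score_min >= 0, cfg$normalized_score_min <= 1,
            cfg$cpe_window >= 0)
  structure(cfg, class = "tnt_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; unknown keys are an error.
#' @return A `tnt_config` object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full dual-omics analysis
#'
#' Reads the configured inputs, quantifies TPM on protein-coding genes,
#' tests differential expression per layer between the two conditions,
#' assigns dual-omics classes, computes translation efficiency and the
#' high-TE set, and (when UTRs and motifs are configured) runs the
#' 3'-UTR motif enrichment of the high-TE genes and the CPE/PAS
#' annotation. Writes result TSVs plus a `summary.json` with the gene
#' counts at every filter stage. Deterministic given inputs and seed.
#'
#' @param config A `tnt_config` from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tnt_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  ann <- stage("annotation", read_annotation(config$annotation))
  sheet <- stage("sample_sheet", read_sample_sheet(config$sample_sheet))
  tx <- stage("counts", read_count_matrix(config$counts_transcriptome))
  tl <- stage("counts", read_count_matrix(config$counts_translatome))
  if (!identical(rownames(tx), rownames(tl)))
    stop("stage 'counts': layers cover different gene sets")

  meta <- function(layer) sheet[sheet$layer == layer, , drop = FALSE]
  mtx <- meta("transcriptome"); mtl <- meta("translatome")
  tx <- tx[, mtx$sample_id, drop = FALSE]
  tl <- tl[, mtl$sample_id, drop = FALSE]

  tx <- filter_protein_coding(tx, ann)
  tl <- filter_protein_coding(tl, ann)
  tpm_tx <- stage("quantify", counts_to_tpm(tx, ann))
  tpm_tl <- stage("quantify", counts_to_tpm(tl, ann))
  expressed <- union(
    expressed_genes(tpm_tx, config$tpm_threshold),
    expressed_genes(tpm_tl, config$tpm_threshold))

  pick <- function(m, meta, cond) m[, meta$stage == cond, drop = FALSE]
  de <- list()
  for (layer in c("transcriptome", "translatome")) {
    counts <- if (layer == "transcriptome") tx else tl
    md <- if (layer == "transcriptome") mtx else mtl
    res <- stage(paste0("de_", layer), nb_wald_test(
      pick(counts, md, config$condition_a),
      pick(counts, md, config$condition_b),
      annotation = ann, tpm_filter = config$tpm_threshold))
    res$layer <- layer
    utils::write.table(res, file.path(config$out_dir,
                                      paste0("de_", layer, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de[[layer]] <- res
  }
  degs <- lapply(de, call_degs, config$p_threshold, config$lfc_threshold)
  classes <- classify_dual_omics(de$transcriptome, de$translatome,
                                 config$p_threshold, config$lfc_threshold)
  utils::write.table(classes, file.path(config$out_dir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  te <- stage("te", compute_te(tpm_tx, tpm_tl, mtx$stage, mtl$stage,
                               config$tpm_threshold))
  utils::write.table(te, file.path(config$out_dir, "te.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  high_te <- high_te_genes(te, config$condition_b,
                           config$log2_te_threshold)

  summary <- list(
    n_genes = nrow(tx),
    n_expressed = length(expressed),
    degs = lapply(degs, lapply, length),
    class_counts = as.list(table(classes$class_label)),
    n_high_te = length(high_te),
    thresholds = config[c("tpm_threshold", "p_threshold", "lfc_threshold",
                          "log2_te_threshold", "motif_pvalue",
                          "normalized_score_min", "cpe_window")],
    seed = config$seed
  )

  if (!is.null(config$utr_fasta) && !is.null(config$motif_meme)) {
    utrs <- stage("utrs", read_utr_fasta(config$utr_fasta))
    pwms <- stage("motifs", read_meme_motifs(config$motif_meme))
    scanned <- intersect(names(utrs), rownames(tx))
    hits <- stage("motif_scan", scan_motifs(utrs[scanned], pwms,
                                            pvalue_threshold = config$motif_pvalue))
    hits <- normalize_and_filter(hits, pwms, config$normalized_score_min)
    utils::write.table(hits, file.path(config$out_dir, "motif_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    target <- intersect(high_te, scanned)
    background <- setdiff(scanned, target)
    if (length(target) >= 2 && length(background) >= 2) {
      occ <- occurrence_table(hits, scanned)
      enr <- stage("motif_enrich",
                   motif_enrichment(occ, target, background))
      utils::write.table(enr, file.path(config$out_dir,
                                        "motif_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$enriched_rbps <- enr$rbp_name[enr$significant]
    }
    cis <- stage("cpe_pas", annotate_cpe_pas(utrs, window = config$cpe_window))
    utils::write.table(cis, file.path(config$out_dir, "cpe_pas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_cpe_pas_paired <- sum(cis$paired)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
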