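# Ground-truth-labelled simulators for every stage of the pipeline.
#
# Counts follow a negative binomial parameterized by mean and dispersion
# alpha with variance mu + alpha * mu^2 (alpha = 0 is a deterministic
# rounding mode, not Poisson). All generators take an explicit seed and
# are bit-reproducible; they restore the caller's RNG state.

.tx_lfc_by_class <- c(I = 0, II = 1, III = 0, IV = -1, V = -1,
                      VI = 1, VII = 1, VIII = -1, unchanged = 0)
.tl_lfc_by_class <- c(I = 1, II = 1, III = -1, IV = -1, V = 0,
                      VI = 0, VII = -1, VIII = 1, unchanged = 0)

#' Simulate paired transcriptome / translatome count matrices
#'
#' Per-gene baseline means are drawn log-normal (log2 mean 5, sd 2 by
#' default, spanning the dynamic range typical of TPM-scale oocyte
#' data). Each gene gets a dual-omics class; the class dictates the
#' planted transcriptome and translatome log2 fold changes (condition B
#' over A) at magnitude `lfc`. The translatome mean is the transcriptome
#' mean times the gene's translation efficiency. Sample columns are
#' scaled to the target depth and counts drawn NB(mean, dispersion).
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_per_condition Replicates per condition per layer (default 3).
#' @param dispersion NB dispersion alpha (default 0.05); 0 means
#'   deterministic rounded means.
#' @param class_fractions Named fractions over the class grid
#'   (I..VIII, unchanged); must sum to 1. Default plants 5% Class I and
#'   5% Class IV.
#' @param lfc Planted |log2 fold change| (default 2).
#' @param te_log2_mean,te_log2_sd Baseline log2 TE distribution
#'   (defaults 0, 0: TE = 1 for every gene unless perturbed by class).
#' @param mean_log2_mean,mean_log2_sd Baseline abundance distribution on
#'   log2 scale (defaults 5 and 2).
#' @param depth Target reads per sample (default 1e6).
#' @param effective_length_range Gene lengths (nt) drawn uniformly in
#'   this range for the bundled annotation (default 500-3000).
#' @param seed Integer seed.
#' @return list: transcriptome, translatome (count matrices, columns
#'   A_1.., B_1..), conditions (label per column), annotation
#'   (protein-coding for every gene), truth (data.frame with planted
#'   class, lfcs and TE per condition).
#' @export
simulate_paired_counts <- function(n_genes = 2000, n_per_condition = 3,
                                   dispersion = 0.05,
                                   class_fractions = c(unchanged = 0.9,
                                                       I = 0.05, IV = 0.05),
                                   lfc = 2,
                                   te_log2_mean = 0, te_log2_sd = 0,
                                   mean_log2_mean = 5, mean_log2_sd = 2,
                                   depth = 1e6,
                                   effective_length_range = c(500, 3000),
                                   seed = 1) {
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (!all(names(class_fractions) %in% names(.tx_lfc_by_class)))
    stop("unknown class label(s): ",
         paste(setdiff(names(class_fractions), names(.tx_lfc_by_class)),
               collapse = ", "))
  if (any(class_fractions < 0)) stop("class_fractions must be >= 0")
  stopifnot(dispersion >= 0, lfc >= 0, n_genes >= 1, n_per_condition >= 1)
  with_seed(seed, {
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    n_per_class <- round(n_genes * class_fractions)
    n_per_class[1] <- n_genes - sum(n_per_class[-1])
    cls <- rep(names(class_fractions), n_per_class)
    cls <- sample(cls)
    mu0 <- 2^stats::rnorm(n_genes, mean_log2_mean, mean_log2_sd)
    te0 <- 2^stats::rnorm(n_genes, te_log2_mean, te_log2_sd)
    tx_lfc <- lfc * .tx_lfc_by_class[cls]
    tl_lfc <- lfc * .tl_lfc_by_class[cls]
    tx_mu <- cbind(A = mu0, B = mu0 * 2^tx_lfc)
    tl_mu <- cbind(A = mu0 * te0, B = mu0 * 2^tx_lfc * te0 * 2^(tl_lfc - tx_lfc))
    draw_layer <- function(mu2) {
      cols <- lapply(c("A", "B"), function(cond) {
        mu <- mu2[, cond] * (depth / sum(mu2[, cond]))
        vapply(seq_len(n_per_condition), function(r) {
          if (dispersion == 0) round(mu)
          else stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
        }, numeric(n_genes))
      })
      m <- do.call(cbind, cols)
      dimnames(m) <- list(gene_id, paste0(rep(c("A", "B"),
                                              each = n_per_condition),
                                          "_", seq_len(n_per_condition)))
      m
    }
    list(
      transcriptome = draw_layer(tx_mu),
      translatome = draw_layer(tl_mu),
      conditions = rep(c("A", "B"), each = n_per_condition),
      annotation = data.frame(
        gene_id = gene_id, gene_name = gene_id,
        biotype = "protein_coding",
        effective_length = round(stats::runif(n_genes,
                                              effective_length_range[1],
                                              effective_length_range[2])),
        stringsAsFactors = FALSE),
      truth = data.frame(
        gene_id = gene_id, class = cls,
        tx_lfc = unname(tx_lfc), tl_lfc = unname(tl_lfc),
        te_a = te0, te_b = te0 * 2^(tl_lfc - tx_lfc),
        base_mean = mu0, stringsAsFactors = FALSE)
    )
  })
}

# Draw one random sequence from a base composition.
#' @noRd
random_seq <- function(len, base_composition) {
  paste(sample(names(base_composition), len, replace = TRUE,
               prob = base_composition), collapse = "")
}

# Sample a motif instance from a PWM's probability rows (DNA alphabet).
#' @noRd
sample_motif_instance <- function(pwm) {
  p <- pwm$probabilities
  paste(apply(p, 1, function(row)
    sample(c("A", "C", "G", "T"), 1, prob = row)), collapse = "")
}

#' Simulate 3'-UTR sequences with planted motif instances
#'
#' Background sequence is i.i.d. from `base_composition`; target-group
#' genes receive Poisson(`target_rate`) planted instances of the motif
#' (sampled from the PWM), background genes Poisson(`background_rate`).
#' Instances are placed uniformly without overlapping each other and
#' their positions are recorded as ground truth.
#'
#' @param n_target,n_background Gene counts per group.
#' @param pwm A [pwm()] object (or NULL to plant nothing).
#' @param target_rate,background_rate Mean planted instances per gene
#'   (defaults 5 and 1, the planted-enrichment study condition).
#' @param length_range UTR lengths drawn uniformly in this range
#'   (default 150-300 nt).
#' @param base_composition Named probabilities for A, C, G, T/U;
#'   default slightly AU-rich (A .3, C .2, G .2, T .3) as in real
#'   3'-UTRs.
#' @param seed Integer seed.
#' @return list: sequences (named; targets "tg_...", background
#'   "bg_..."), truth (gene_id, group, n_planted, positions as
#'   semicolon-separated 0-based starts).
#' @export
simulate_utrs <- function(n_target = 200, n_background = 1000, pwm = NULL,
                          target_rate = 5, background_rate = 1,
                          length_range = c(150, 300),
                          base_composition = c(A = 0.3, C = 0.2,
                                               G = 0.2, T = 0.3),
                          seed = 1) {
  names(base_composition) <- chartr("U", "T", toupper(names(base_composition)))
  with_seed(seed, {
    ids <- c(sprintf("tg_%04d", seq_len(n_target)),
             sprintf("bg_%04d", seq_len(n_background)))
    group <- rep(c("target", "background"), c(n_target, n_background))
    rate <- ifelse(group == "target", target_rate, background_rate)
    L <- nrow(pwm$probabilities %||% matrix(nrow = 0, ncol = 4))
    seqs <- character(length(ids))
    planted <- character(length(ids))
    nplant <- integer(length(ids))
    for (i in seq_along(ids)) {
      len <- round(stats::runif(1, length_range[1], length_range[2]))
      s <- strsplit(random_seq(len, base_composition), "")[[1]]
      pos <- integer(0)
      if (!is.null(pwm)) {
        if (L > len) stop("motif longer than UTR (", L, " > ", len, ")")
        k <- stats::rpois(1, rate[i])
        tries <- 0
        while (length(pos) < k && tries < 200) {
          cand <- sample.int(len - L + 1L, 1) - 1L
          if (!any(abs(cand - pos) < L)) {
            inst <- strsplit(sample_motif_instance(pwm), "")[[1]]
            s[(cand + 1):(cand + L)] <- inst
            pos <- c(pos, cand)
          }
          tries <- tries + 1
        }
      }
      seqs[i] <- paste(s, collapse = "")
      planted[i] <- paste(sort(pos), collapse = ";")
      nplant[i] <- length(pos)
    }
    names(seqs) <- ids
    list(sequences = seqs,
         truth = data.frame(gene_id = ids, group = group,
                            n_planted = nplant, positions = planted,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate 3'-UTRs with a planted CPE-PAS pair at a known gap
#'
#' Fixture generator for the cis-element scanner: each sequence carries
#' exactly one CPE and one PAS separated by `gap` nt. The background is
#' G/C-only by default so that no accidental CPE or PAS can arise and
#' the planted configuration is the exact truth.
#'
#' @param n_genes Number of sequences.
#' @param gap Nucleotides between the CPE's end and the PAS's start.
#' @param cpe,pas Element sequences to plant (defaults UUUUAU, AAUAAA).
#' @param utr_length Sequence length (nt), default 250.
#' @param base_composition Background composition; default G/C only.
#' @param seed Integer seed.
#' @return list: sequences (named), truth (gene_id, cpe_start,
#'   pas_start, gap).
#' @export
simulate_cpe_pas_utrs <- function(n_genes = 20, gap = 34,
                                  cpe = "UUUUAU", pas = "AAUAAA",
                                  utr_length = 250,
                                  base_composition = c(G = 0.5, C = 0.5),
                                  seed = 1) {
  cpe <- chartr("U", "T", toupper(cpe))
  pas <- chartr("U", "T", toupper(pas))
  need <- nchar(cpe) + gap + nchar(pas)
  if (need > utr_length)
    stop("utr_length too short for the requested gap")
  with_seed(seed, {
    ids <- sprintf("utr_%03d", seq_len(n_genes))
    seqs <- character(n_genes)
    cpe_start <- integer(n_genes)
    for (i in seq_len(n_genes)) {
      s <- strsplit(random_seq(utr_length, base_composition), "")[[1]]
      c0 <- sample.int(utr_length - need + 1L, 1) - 1L
      s[(c0 + 1):(c0 + nchar(cpe))] <- strsplit(cpe, "")[[1]]
      p0 <- c0 + nchar(cpe) + gap
      s[(p0 + 1):(p0 + nchar(pas))] <- strsplit(pas, "")[[1]]
      seqs[i] <- paste(s, collapse = "")
      cpe_start[i] <- c0
    }
    names(seqs) <- ids
    list(sequences = seqs,
         truth = data.frame(gene_id = ids, cpe_start = cpe_start,
                            pas_start = cpe_start + nchar(cpe) + gap,
                            gap = gap, stringsAsFactors = FALSE))
  })
}

#' Simulate paired libraries with ERCC-style spike-ins
#'
#' Transcriptome libraries are multinomial draws over endogenous genes
#' plus spike-ins whose expected read share is `spike_fraction`. In the
#' translatome, endogenous mRNAs are carried through while each spike-in
#' read is retained by binomial thinning with probability
#' `nonspecific_probability` (spike-ins are not translated, so any
#' retention models non-specific bead binding).
#'
#' @param n_spikes Number of spike-in species (default 92, the standard
#'   mix size).
#' @param n_genes Number of endogenous genes (default 2000).
#' @param spike_fraction Expected spike-in read share of the
#'   transcriptome library (default 0.02).
#' @param nonspecific_probability Per-molecule non-specific capture
#'   probability in [0, 1].
#' @param depth Reads per transcriptome library (default 1e6).
#' @param n_samples Number of paired libraries (default 2).
#' @param seed Integer seed.
#' @return list: transcriptome, translatome (count matrices including
#'   spike rows), spike_ids, truth (the planted probability).
#' @export
simulate_spikeins <- function(n_spikes = 92, n_genes = 2000,
                              spike_fraction = 0.02,
                              nonspecific_probability = 0.167,
                              depth = 1e6, n_samples = 2, seed = 1) {
  stopifnot(nonspecific_probability >= 0, nonspecific_probability <= 1,
            spike_fraction > 0, spike_fraction < 1)
  with_seed(seed, {
    gid <- sprintf("gene%05d", seq_len(n_genes))
    sid <- sprintf("ERCC-%05d", seq_len(n_spikes))
    w_g <- 2^stats::rnorm(n_genes, 0, 2)
    w_s <- 2^stats::rnorm(n_spikes, 0, 2)
    prob <- c(w_g / sum(w_g) * (1 - spike_fraction),
              w_s / sum(w_s) * spike_fraction)
    tx <- vapply(seq_len(n_samples), function(j)
      stats::rmultinom(1, depth, prob)[, 1], numeric(n_genes + n_spikes))
    tl_spike <- matrix(
      stats::rbinom(n_spikes * n_samples,
                    size = as.integer(tx[n_genes + seq_len(n_spikes), ]),
                    prob = nonspecific_probability),
      n_spikes, n_samples)
    tl <- rbind(tx[seq_len(n_genes), , drop = FALSE], tl_spike)
    dimnames(tx) <- dimnames(tl) <-
      list(c(gid, sid), paste0("s", seq_len(n_samples)))
    list(transcriptome = tx, translatome = tl, spike_ids = sid,
         truth = list(nonspecific_probability = nonspecific_probability))
  })
}
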