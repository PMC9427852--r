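---
title: "Dual-omics transcriptome/translatome analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-omics transcriptome/translatome analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its methods: the models behind
each stage, the parameters that matter, the numerical choices, and the
points where the design was genuinely open and a convention had to be
fixed. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The setting

In paired transcriptome + translatome experiments the same lysate is
split: one part is sequenced as total mRNA (transcriptome), the other
after affinity capture of actively translating ribosomes (translatome).
Both layers yield gene-level count matrices over the same genes and
samples. In systems under translational control — maturing oocytes above
all — the interesting signal is the *divergence* between the layers: a
gene may be translationally activated while its mRNA abundance does not
move. The package quantifies that divergence three ways: per-layer
differential expression between two conditions, translation efficiency
(TE), and a joint class assignment; and then asks what distinguishes the
translationally activated mRNAs, via their 3'-UTR sequence elements.

## Quantification

TPM is computed from gene-level counts and an effective gene length:
$\mathrm{TPM}_g = 10^6 \, (c_g/l_g) / \sum_j (c_j/l_j)$ per sample.
The effective length is whatever the annotation table supplies —
`read_gtf_annotation()` derives the union-exon length, but a
transcript-model length can be substituted; the choice is an input, not
something the package guesses. Downstream analyses use protein-coding
genes only, and expressed-gene sets use a strict `TPM > 1` rule (a gene
at exactly the threshold is out). Sample concordance is Pearson
correlation on `log2(TPM + 1)`; the pseudocount of 1 is the conventional
display transform and is configurable.

## The negative-binomial Wald test

Counts for gene $g$ in sample $j$ are modelled
$K_{gj} \sim \mathrm{NB}(s_j q_{g,\mathrm{cond}(j)}, \alpha_g)$ with
variance $\mu + \alpha\mu^2$. The stages are:

1. **Size factors**: median-of-ratios against the per-gene geometric
   mean over samples (genes with any zero excluded from the reference),
   rescaled to unit geometric mean.
2. **Dispersion**: per-gene method-of-moments
   $\hat\alpha = (s^2 - \bar m)/\bar m^2$ from the pooled within-condition
   variance of normalized counts, then shrunk toward a fitted trend
   $\alpha(\mu) = a_0 + a_1/\mu$ (least squares on the gene-wise
   estimates). The blend is **arithmetic**,
   $\alpha = (1-w)\,\hat\alpha + w\,\alpha_{\mathrm{tr}}(\mu)$ with
   $w = 0.7$ by default: blending on the log scale looks natural but
   systematically under-estimates dispersion (the geometric mean of a
   noisy, roughly unbiased estimator sits well below its mean), which
   makes the Wald test anticonservative at three replicates per group.
   With one replicate per group a single pooled dispersion is used and a
   warning emitted. A known dispersion can be supplied, which disables
   estimation entirely (used by the likelihood-oracle test).
3. **Fit and test**: the group log-means are fitted by Fisher scoring
   (score $\sum (k-\mu)/(1+\alpha\mu)$, information
   $\sum \mu/(1+\alpha\mu)$), the Wald statistic is
   $\log_2\mathrm{FC}/\mathrm{SE}$ with the SE from the expected
   information, and the p-value is the two-sided normal tail. A
   condition with zero counts gets a pseudo-mean floor of 0.5 normalized
   counts so the fold change stays finite.

Deliberate omissions, stated openly: no independent filtering, no
outlier handling, no fold-change shrinkage, and no multiple-testing
adjustment — DEG calls use the raw `p < 0.05`, `|log2FC| > 1`
convention of the analyses this package reproduces, with both
inequalities strict. The fold-change direction is always *second
condition over first*.

Calibration is part of the test suite: on 2000 simulated null genes
(dispersion 0.1, 3 vs 3) the fraction at `p < 0.05` must fall in
[0.03, 0.08] and the p-value distribution must be near-uniform
(Kolmogorov–Smirnov distance < 0.05).

## TE and the dual-omics class grid

TE is the translatome/transcriptome TPM ratio. Replicates are combined
on the log scale — per condition the package reports the geometric mean
TPM of each layer, so TE is also the geometric mean of per-replicate
ratios and `log2_te` is a plain mean of logs. The expression filter
(both layers' TPM > 1 in that condition, strictly) is applied to those
geometric means; filtered genes are absent from the output rather than
carrying undefined values. High-TE sets use strict thresholds with the
conventional presets `log2TE > 0, 1, 2` (TE > 1, 2, 4).

Each gene's (transcriptome, translatome) DEG calls — up, constant, down,
where constant is simply "not a DEG at the thresholds", with no
equivalence testing — place it on a 3×3 grid. Two cells have fixed
meanings from the analyses this package models: Class I = (constant,
up), Class IV = (down, down). The literature this grid descends from
does not define the remaining six labels recoverably, so the package
fixes a convention, chosen so that Classes I, III, IV and V are exactly
the transcriptionally constant-or-down classes:

| transcriptome | translatome | class |
|---|---|---|
| constant | up | I |
| up | up | II |
| constant | down | III |
| down | down | IV |
| down | constant | V |
| up | constant | VI |
| up | down | VII |
| down | up | VIII |
| constant | constant | unchanged |

This convention is a package decision, not an external standard; the
grid is a partition, and reversing the condition order maps each class
to its mirror (I ↔ III, II ↔ IV, etc.).

## PWM scanning and exact score p-values

Motifs are position probability matrices over {A, C, G, U} (MEME minimal
format; T ≡ U, zero cells floored at $10^{-4}$ and rows renormalized).
Scanning is FIMO-style on the sense strand only: each window of length
$L$ scores $\sum_i \log_2 p_i(b_i)/\pi(b_i)$ against the background
$\pi$ (uniform by default).

Per-position scores are rounded once to a fixed granularity of $10^{-3}$
log2 units; windows are scored by summing the rounded cells, and the
score p-value — $P(\text{score} \ge s)$ for an i.i.d. background window
— is computed by dynamic programming over the integerized score
distribution. Because scanner and DP share one grid, the p-value is
*exact* for the reported score, not an approximation; the test suite
verifies equality with exhaustive $4^L$ enumeration to $10^{-6}$ for all
$L \le 8$. Hits are retained at score p-value < $10^{-4}$ (the usual
scanning default). Note the attainable floor: a length-$L$ motif cannot
have a p-value below $4^{-L}$ under a uniform background, so motifs
shorter than 7 nt can never pass the $10^{-4}$ default — the bundled
demo compendium uses widths 7–8 for this reason, and callers scanning
short elements should raise the threshold deliberately.

The post-scan "strict threshold" is min–max normalization of the score
to the PWM's *attainable* range (0 at the worst window, 1 at the
consensus), keeping hits at `normalized_score >= 0.8`. Normalizing to
the attainable range rather than the observed hit distribution keeps the
filter deterministic and dataset-independent. Occurrence is the raw
count of retained hits of any of an RBP's motifs per gene (per-kb
optional; unnormalized is the default because the statistic this mirrors
is a plain occurrence count).

Enrichment compares per-gene occurrences between a target set (e.g.
high-TE genes) and a background with a one-sided Welch t-test
(target > background; Welch because nothing guarantees equal variances),
a log2 fold change of means with pseudo-occurrence $\varepsilon = 0.01$,
and the strict raw-p rule `log2FC > 1 and p < 1e-5` — again with no
multiplicity correction, prominently by design. Co-occurrence counts are
upset-style: for each RBP subset, the number of genes carrying at least
one retained hit of *every* member.

## CPE / PAS

The scanner takes IUPAC consensus strings. The defaults — CPE
{UUUUAU, UUUUAAU}, PAS {AAUAAA, AUUAAA} — are the standard literature
consensus sets, flagged as package defaults rather than values inherited
from any particular study, and fully configurable. Pairing uses the
distance between nearest element ends (0 when overlapping), with an
inclusive window (`gap <= 100` nt by default); "within 100 nt" phrasings
are ambiguous between start–start and end–start measures, and the
nearest-end reading is the one that makes an overlapping CPE/PAS pair
trivially paired. Enlarging the window can only add pairs.

## Spike-in non-specific capture

Spike-ins added before ribosome capture are not translated, so their
presence in the translatome is non-specific binding. With
$f_{\mathrm{in}}$ the spike-in read share of the transcriptome library
and $f_{\mathrm{cap}}$ the share of the translatome library, the
estimator is $f_{\mathrm{cap}}/f_{\mathrm{in}}$. The source analyses
report such a fraction without printing their estimator; the
ratio-of-fractions form is this package's documented interpretation. It
is depth-invariant in expectation and exactly zero under fully specific
capture; both the per-sample mean and a pooled (summed-counts) estimate
are returned because which of the two a given report means is usually
unstated. The estimator carries a small positive bias of order the
spike-in library share (the translatome denominator loses the
non-captured spike mass); at the 2% default share this is well inside
the simulation's ±0.02 acceptance band.

## Maturation statistics

`chi_square_2x2()` is Pearson's chi-square with 1 df via
`stats::chisq.test`, continuity correction off by default — the
uncorrected statistic is the one that reproduces the printed worked
example (statistic 4.57143, p 0.03251 on the 6/10 vs 12/4 table) — with
the Yates option exposed. `chi_square_pvalue()` gives the upper tail for
a reported statistic, and `maturation_rate()` is a guarded percentage.

## The synthetic-data generators

`simulate_paired_counts()` emulates exactly the structure the analysis
assumes: log-normal baseline abundances (log2 mean 5, sd 2 — arbitrary
but spanning the observed TPM range of such data), a planted class per
gene dictating transcriptome/translatome log2 fold changes of magnitude
2, translatome means tied to the transcriptome by a per-gene TE, columns
scaled to a target depth, NB noise at a stated dispersion
(`Var = μ + αμ²`; α = 0 is a deterministic rounding mode). The defaults
— 2000 genes, 3 replicates per condition, dispersion 0.05 (0.1 for null
calibration), depth $10^6$ — are the study conditions of the test suite
and acceptance script, stated here as the package's chosen problem
sizes. `simulate_utrs()` plants PWM-sampled motif instances at
Poisson(5) / Poisson(1) rates in target/background genes of slightly
AU-rich random sequence; `simulate_cpe_pas_utrs()` plants one CPE–PAS
pair at a chosen gap on a G/C-only background so that the planted
configuration is provably the only one present; and
`simulate_spikeins()` thins spike-in molecules into the translatome with
a known binomial probability (0.167 in the acceptance run, 2% spike
library share). All generators take a seed, are bit-reproducible, and
restore the caller's RNG state.

What the simulations deliberately do **not** emulate: GC/length biases,
batch effects, sample swaps, UMI duplication, zero inflation beyond NB,
correlated gene programs, or read-level artefacts. Passing the planted
recovery tests therefore demonstrates the correctness and calibration of
the estimators under their own model, not robustness to every failure
mode of real libraries.

## Orchestration

`run_pipeline()` wires the stages over file-based inputs (TSV matrices,
FASTA UTRs, MEME motifs, YAML config with rejected unknown keys) and
writes per-stage TSVs plus a `summary.json` of gene counts at every
filter stage, the thresholds used, and the seed; identical inputs and
seed give byte-identical summaries. This package's users work in R, so
the exported functions *are* the command-line surface; the only shell
entry point shipped is `scripts/acceptance.R`.

## Known limitations

- Single-factor, two-condition designs only; no likelihood-ratio tests
  or FDR control (the raw-p conventions are reproduced as-is).
- The NB Wald test is a minimal reimplementation: results will track,
  but not numerically equal, mature DE packages with shrinkage and
  outlier machinery.
- Exact DP p-values assume an i.i.d. background; no Markov background
  model.
- CPE/PAS consensus defaults are literature-standard but not sourced
  from any one study; treat them as a starting point.
- The spike-in estimator attributes *all* translatome spike signal to
  non-specific binding; carry-over contamination would be
  indistinguishable.
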