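# CPE / PAS cis-element detection in 3'-UTRs.
#
# Cytoplasmic polyadenylation elements (CPE, canonically UUUUAU-like) and
# polyadenylation signals (PAS, AAUAAA-like) jointly mark mRNAs for
# cytoplasmic polyadenylation and translational activation during oocyte
# maturation; a CPE near a PAS is the functional configuration.

#' Scan a sequence for an IUPAC consensus
#'
#' All (possibly overlapping) exact IUPAC matches on the sense strand.
#' Sequence and pattern are uppercased and U is treated as T.
#'
#' @param sequence A single DNA/RNA sequence string.
#' @param pattern IUPAC nucleotide pattern (non-empty).
#' @return Integer vector of 0-based match start positions.
#' @export
scan_consensus <- function(sequence, pattern) {
  if (!nzchar(pattern)) stop("empty pattern")
  pat <- chartr("U", "T", toupper(pattern))
  if (grepl("[^ACGTRYSWKMBDHVN]", pat))
    stop("pattern contains non-IUPAC characters: ", pattern)
  seq <- chartr("U", "T", toupper(sequence))
  if (nchar(seq) < nchar(pat)) return(integer(0))
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                fixed = FALSE)
  as.integer(Biostrings::start(m)) - 1L
}

#' Pair CPE and PAS elements within a proximity window
#'
#' The gap between two elements is the distance between their nearest
#' ends (0 if they overlap or abut); a CPE-PAS pair is reported when the
#' gap is at most `window` nucleotides (inclusive).
#'
#' @param cpe_positions,pas_positions Integer vectors of 0-based starts.
#' @param cpe_width,pas_width Element widths (nt), scalar or one per
#'   position.
#' @param window Maximum gap (default 100, inclusive `<=`).
#' @return list(paired = flag, pairs = data.frame(cpe_start, pas_start,
#'   gap)).
#' @export
pair_within <- function(cpe_positions, pas_positions,
                        cpe_width = 6L, pas_width = 6L, window = 100) {
  stopifnot(window >= 0)
  if (!length(cpe_positions) || !length(pas_positions))
    return(list(paired = FALSE,
                pairs = data.frame(cpe_start = integer(0),
                                   pas_start = integer(0),
                                   gap = integer(0))))
  cw <- rep_len(cpe_width, length(cpe_positions))
  pw <- rep_len(pas_width, length(pas_positions))
  grid <- expand.grid(i = seq_along(cpe_positions),
                      j = seq_along(pas_positions))
  c1 <- cpe_positions[grid$i]; c2 <- c1 + cw[grid$i]
  p1 <- pas_positions[grid$j]; p2 <- p1 + pw[grid$j]
  gap <- pmax(0L, pmax(c1 - p2, p1 - c2))
  keep <- gap <= window
  pairs <- data.frame(cpe_start = c1[keep], pas_start = p1[keep],
                      gap = as.integer(gap[keep]))
  list(paired = any(keep), pairs = pairs)
}

#' Annotate a gene set with CPE / PAS elements and their pairing
#'
#' Scans each 3'-UTR for every CPE and PAS consensus and reports counts,
#' positions and whether at least one CPE lies within `window` nt of a
#' PAS. The default consensus sets (CPE: UUUUAU, UUUUAAU; PAS: AAUAAA,
#' AUUAAA) follow the standard CPE/PAS literature definitions and are
#' fully configurable.
#'
#' @param utrs Named character vector of 3'-UTR sequences.
#' @param cpe_patterns,pas_patterns IUPAC consensus vectors (non-empty).
#' @param window Pairing window in nt (default 100).
#' @return data.frame: gene_id, n_cpe, n_pas, paired, min_gap,
#'   cpe_positions, pas_positions (semicolon-separated 0-based starts).
#'   Genes with missing (NA or empty) sequences are skipped with a
#'   message.
#' @export
annotate_cpe_pas <- function(utrs,
                             cpe_patterns = c("UUUUAU", "UUUUAAU"),
                             pas_patterns = c("AAUAAA", "AUUAAA"),
                             window = 100) {
  if (!length(cpe_patterns) || !length(pas_patterns))
    stop("pattern lists must be non-empty")
  bad <- is.na(utrs) | !nzchar(utrs)
  if (any(bad)) {
    message("skipping ", sum(bad), " gene(s) without UTR sequence")
    utrs <- utrs[!bad]
  }
  scan_all <- function(seq, patterns) {
    pos <- lapply(patterns, function(p) scan_consensus(seq, p))
    width <- rep(nchar(patterns), lengths(pos))
    data.frame(start = unlist(pos, use.names = FALSE) %||% integer(0),
               width = width %||% integer(0))
  }
  rows <- lapply(names(utrs), function(g) {
    cpe <- scan_all(utrs[[g]], cpe_patterns)
    pas <- scan_all(utrs[[g]], pas_patterns)
    pr <- pair_within(cpe$start, pas$start, cpe$width, pas$width, window)
    data.frame(
      gene_id = g,
      n_cpe = nrow(cpe), n_pas = nrow(pas),
      paired = pr$paired,
      min_gap = if (nrow(pr$pairs)) min(pr$pairs$gap) else NA_integer_,
      cpe_positions = paste(sort(cpe$start), collapse = ";"),
      pas_positions = paste(sort(pas$start), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
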