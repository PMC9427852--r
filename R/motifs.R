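# RNA motif (PWM) machinery: MEME minimal format parsing, FIMO-style
# log-odds scanning on the sense strand, and exact score p-values by
# dynamic programming over the integerized score distribution.
#
# Scores are integerized at a fixed granularity (default 1e-3 log2 units,
# the documented bin width): each per-position log2(p/bg) cell is rounded
# to the grid once, windows are scored by summing the gridded cells, and
# the p-value DP runs on the same grid, so the reported p-value is exact
# for the reported score.

.pwm_granularity <- 1e-3
.pwm_floor <- 1e-4

#' Construct a position weight matrix object
#'
#' @param probabilities L x 4 matrix of per-position probabilities over
#'   the RNA alphabet A, C, G, U (columns in that order). Rows are
#'   renormalized after flooring zero cells at 1e-4.
#' @param motif_id Unique motif identifier.
#' @param rbp_name RNA-binding protein the motif belongs to (several
#'   motifs may share one RBP). Defaults to `motif_id`.
#' @param source Free-text provenance tag.
#' @return Object of class `pwm`.
#' @export
pwm <- function(probabilities, motif_id, rbp_name = motif_id, source = "") {
  probabilities <- as.matrix(probabilities)
  if (ncol(probabilities) != 4)
    stop("PWM '", motif_id, "': need 4 columns (A, C, G, U)")
  L <- nrow(probabilities)
  if (L < 1 || L > 30)
    stop("PWM '", motif_id, "': length must be in 1..30, got ", L)
  if (any(probabilities < 0) || any(!is.finite(probabilities)))
    stop("PWM '", motif_id, "': probabilities must be finite and >= 0")
  rs <- rowSums(probabilities)
  if (any(rs <= 0))
    stop("PWM '", motif_id, "': a position has zero total probability")
  if (any(abs(rs - 1) > 1e-3))
    warning("PWM '", motif_id, "': row sums off by more than 1e-3; renormalized")
  probabilities <- pmax(probabilities, .pwm_floor)
  probabilities <- probabilities / rowSums(probabilities)
  colnames(probabilities) <- c("A", "C", "G", "U")
  structure(
    list(motif_id = motif_id, rbp_name = rbp_name,
         probabilities = probabilities, source = source),
    class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "(", x$rbp_name, "), length",
      nrow(x$probabilities), "\n")
  print(round(x$probabilities, 3))
  invisible(x)
}

#' Load a motif compendium in MEME minimal format
#'
#' Parses MEME minimal motif files (the interchange format of the common
#' RBP motif databases). T and U are treated as the same letter. Zero
#' probability cells are floored at 1e-4 and rows renormalized.
#'
#' @param path Path to a MEME minimal file.
#' @return Named list of [pwm()] objects (names = motif ids). An empty
#'   file yields an empty list with a warning.
#' @export
read_meme_motifs <- function(path) {
  lines <- trimws(readLines(path))
  midx <- grep("^MOTIF\\b", lines)
  if (!length(midx)) {
    warning("no motifs found in ", path)
    return(structure(list(), names = character(0)))
  }
  bg <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  bidx <- grep("^Background letter frequencies", lines)
  if (length(bidx)) {
    tok <- strsplit(paste(lines[bidx[1] + 1]), "\\s+")[[1]]
    if (length(tok) >= 8) {
      v <- as.numeric(tok[seq(2, 8, 2)])
      nm <- toupper(tok[seq(1, 7, 2)])
      nm[nm == "T"] <- "U"
      if (!anyNA(v) && all(nm %in% names(bg))) bg[nm] <- v
    }
  }
  out <- list()
  bounds <- c(midx, length(lines) + 1L)
  for (k in seq_along(midx)) {
    block <- lines[midx[k]:(bounds[k + 1] - 1L)]
    tok <- strsplit(block[1], "\\s+")[[1]]
    if (length(tok) < 2) stop("MOTIF line without an id in ", path)
    id <- tok[2]
    rbp <- if (length(tok) >= 3) tok[3] else id
    if (id %in% names(out)) stop("duplicate motif id '", id, "'")
    h <- grep("^letter-probability matrix", block)
    if (!length(h))
      stop("motif '", id, "': no letter-probability matrix header")
    w <- suppressWarnings(
      as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[h[1]])))
    rows <- block[-seq_len(h[1])]
    rows <- rows[nzchar(rows)]
    num <- suppressWarnings(lapply(strsplit(rows, "\\s+"), as.numeric))
    ok <- vapply(num, function(x) length(x) == 4 && !anyNA(x), logical(1))
    stopat <- if (all(ok)) length(num) else which(!ok)[1] - 1L
    num <- num[seq_len(stopat)]
    if (!is.na(w) && length(num) < w)
      stop("motif '", id, "': matrix has ", length(num),
           " rows but header says w=", w)
    if (!is.na(w)) num <- num[seq_len(w)]
    if (!length(num)) stop("motif '", id, "': empty probability matrix")
    mat <- do.call(rbind, num)
    out[[id]] <- pwm(mat, motif_id = id, rbp_name = rbp, source = path)
  }
  attr(out, "background") <- bg
  out
}

# Integerized log2-odds score matrix for one pwm: round(log2(p/bg)/gran).
#' @noRd
pwm_int_scores <- function(pwm, background, granularity = .pwm_granularity) {
  s <- log2(pwm$probabilities / rep(background, each = nrow(pwm$probabilities)))
  storage.mode(s) <- "double"
  matrix(as.integer(round(s / granularity)), nrow = nrow(s))
}

# Exact distribution of the integer window score under the background
# model: list(base = minimum attainable integer score, surv = vector of
# P(score >= base + i - 1)).
#' @noRd
pwm_score_survival <- function(si, background) {
  L <- nrow(si)
  mins <- apply(si, 1, min)
  v <- 1
  for (i in seq_len(L)) {
    shifts <- si[i, ] - mins[i]
    w <- numeric(length(v) + max(shifts))
    for (b in 1:4) {
      idx <- seq_along(v) + shifts[b]
      w[idx] <- w[idx] + v * background[b]
    }
    v <- w
  }
  surv <- rev(cumsum(rev(v)))
  list(base = sum(mins), surv = surv)
}

#' Exact PWM score p-values
#'
#' P(window score >= s) for i.i.d. background sequence, computed by
#' dynamic programming over the integerized score distribution (exact for
#' the granularity-rounded scoring scheme the scanner itself uses).
#'
#' @param pwm A [pwm()] object.
#' @param scores Numeric vector of window log2-odds scores (as reported
#'   by [scan_pwm()]).
#' @param background Background probabilities for A, C, G, U.
#' @return Numeric vector of p-values in (0, 1].
#' @export
pwm_score_pvalue <- function(pwm, scores, background = rep(0.25, 4)) {
  si <- pwm_int_scores(pwm, background)
  sv <- pwm_score_survival(si, background)
  k <- as.integer(round(scores / .pwm_granularity)) - sv$base + 1L
  p <- numeric(length(k))
  p[k <= 0] <- 1
  inr <- k >= 1 & k <= length(sv$surv)
  p[inr] <- sv$surv[k[inr]]
  p[k > length(sv$surv)] <- 0
  pmin(pmax(p, 0), 1)
}

# Encode an uppercase DNA/RNA string as 1..4 with NA for anything else.
#' @noRd
encode_seq <- function(seq) {
  x <- charToRaw(chartr("U", "T", toupper(seq)))
  code <- rep(NA_integer_, length(x))
  code[x == charToRaw("A")] <- 1L
  code[x == charToRaw("C")] <- 2L
  code[x == charToRaw("G")] <- 3L
  code[x == charToRaw("T")] <- 4L
  code
}

#' Scan sequences with one PWM
#'
#' Slides the motif over the sense strand of each sequence, scoring every
#' window as the summed log2 likelihood ratio of motif over background,
#' and keeps windows whose exact score p-value (see
#' [pwm_score_pvalue()]) is below `pvalue_threshold`. Overlapping hits
#' are allowed; windows containing N are skipped; sequences shorter than
#' the motif yield no hits. Coordinates are 0-based, half-open.
#'
#' @param sequences Named character vector of sequences (names = gene
#'   ids); DNA or RNA alphabet, case-insensitive.
#' @param pwm A [pwm()] object.
#' @param background Background probabilities for A, C, G, U; default
#'   uniform.
#' @param pvalue_threshold Score p-value cutoff for retaining a window
#'   (strict `<`), default 1e-4.
#' @return data.frame: gene_id, motif_id, rbp_name, start, end,
#'   raw_score, score_pvalue, normalized_score.
#' @export
scan_pwm <- function(sequences, pwm, background = rep(0.25, 4),
                     pvalue_threshold = 1e-4) {
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  si <- pwm_int_scores(pwm, background)
  L <- nrow(si)
  sv <- pwm_score_survival(si, background)
  smin <- sum(apply(si, 1, min))
  smax <- sum(apply(si, 1, max))
  res <- vector("list", length(sequences))
  for (s in seq_along(sequences)) {
    code <- encode_seq(sequences[[s]])
    n <- length(code)
    if (n < L) next
    nw <- n - L + 1L
    tot <- rep(0L, nw)
    for (i in seq_len(L)) {
      tot <- tot + si[i, ][code[i:(i + nw - 1L)]]
    }
    ok <- which(!is.na(tot))
    if (!length(ok)) next
    k <- tot[ok] - sv$base + 1L
    pv <- sv$surv[pmin(pmax(k, 1L), length(sv$surv))]
    pv[k <= 0] <- 1
    keep <- pv < pvalue_threshold
    if (!any(keep)) next
    sc <- tot[ok][keep]
    ok <- ok[keep]
    res[[s]] <- data.frame(
      gene_id = names(sequences)[s],
      motif_id = pwm$motif_id,
      rbp_name = pwm$rbp_name,
      start = ok - 1L,
      end = ok - 1L + L,
      raw_score = sc * .pwm_granularity,
      score_pvalue = pv[keep],
      normalized_score = if (smax > smin)
        (sc - smin) / (smax - smin) else NA_real_,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) empty_hits() else out
}

#' @noRd
empty_hits <- function() {
  data.frame(gene_id = character(0), motif_id = character(0),
             rbp_name = character(0), start = integer(0), end = integer(0),
             raw_score = numeric(0), score_pvalue = numeric(0),
             normalized_score = numeric(0), stringsAsFactors = FALSE)
}

#' Scan sequences with a motif compendium
#'
#' @param sequences Named character vector of sequences.
#' @param pwms List of [pwm()] objects (e.g. from [read_meme_motifs()]).
#' @param ... Passed to [scan_pwm()].
#' @return Combined hit data.frame across all motifs.
#' @export
scan_motifs <- function(sequences, pwms, ...) {
  out <- lapply(pwms, function(p) scan_pwm(sequences, p, ...))
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_hits())
  rownames(out) <- NULL
  out
}

#' Min-max score normalization and strict filtering of motif hits
#'
#' Normalizes each hit's score to the PWM's attainable score range
#' (deterministic and dataset-independent: 0 at the worst attainable
#' window, 1 at the consensus) and keeps hits at or above
#' `min_normalized_score`. A degenerate PWM whose attainable maximum
#' equals its minimum is dropped with a warning.
#'
#' @param hits Hit data.frame from [scan_pwm()] / [scan_motifs()].
#' @param pwms The list of PWMs the hits were produced with.
#' @param min_normalized_score Retention threshold in [0, 1]
#'   (inclusive `>=`), default 0.8.
#' @param background Background probabilities used at scan time.
#' @return Filtered hit data.frame with recomputed normalized_score.
#' @export
normalize_and_filter <- function(hits, pwms, min_normalized_score = 0.8,
                                 background = rep(0.25, 4)) {
  background <- background / sum(background)
  if (!nrow(hits)) return(hits)
  keep <- logical(nrow(hits))
  for (id in unique(hits$motif_id)) {
    p <- pwms[[id]]
    if (is.null(p)) stop("hits reference unknown motif '", id, "'")
    si <- pwm_int_scores(p, background)
    smin <- sum(apply(si, 1, min))
    smax <- sum(apply(si, 1, max))
    rows <- hits$motif_id == id
    if (smax <= smin) {
      warning("motif '", id, "' has a degenerate score range; dropped")
      next
    }
    ns <- (round(hits$raw_score[rows] / .pwm_granularity) - smin) /
      (smax - smin)
    hits$normalized_score[rows] <- ns
    keep[rows] <- ns >= min_normalized_score
  }
  hits[keep, , drop = FALSE]
}
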