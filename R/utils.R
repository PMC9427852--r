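# Internal validators shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_count_matrix <- function(x, name = "counts") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(x)))
    stop(name, " must carry gene_ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop(name, " has duplicated gene_ids", call. = FALSE)
  if (any(x < 0)) stop(name, " contains negative values", call. = FALSE)
  invisible(x)
}

#' @noRd
assert_annotation <- function(annotation) {
  needed <- c("gene_id", "biotype", "effective_length")
  if (!is.data.frame(annotation) || !all(needed %in% names(annotation)))
    stop("annotation must be a data.frame with columns gene_id, biotype, effective_length",
         call. = FALSE)
  if (anyDuplicated(annotation$gene_id))
    stop("annotation gene_id values must be unique", call. = FALSE)
  if (any(annotation$effective_length < 1))
    stop("effective_length must be >= 1 for every gene", call. = FALSE)
  invisible(annotation)
}

# Match annotation rows to matrix rows; error names the first missing gene.
#' @noRd
annotation_for <- function(mat, annotation) {
  assert_annotation(annotation)
  idx <- match(rownames(mat), annotation$gene_id)
  if (anyNA(idx)) {
    missing <- rownames(mat)[which(is.na(idx))[1]]
    stop("no annotation for gene '", missing, "'", call. = FALSE)
  }
  annotation[idx, , drop = FALSE]
}

# Scoped RNG: run code under a given seed without disturbing the caller's RNG.
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
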