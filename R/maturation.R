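#' Chi-square test on a 2x2 maturation outcome table
#'
#' Pearson chi-square with 1 degree of freedom for a treated-vs-control
#' by matured-vs-not table, via [stats::chisq.test()]. The continuity
#' correction is off by default (the uncorrected statistic is the one
#' conventionally reported for these maturation comparisons).
#'
#' @param table 2x2 matrix of non-negative integer counts (rows =
#'   groups, columns = matured / not matured), or a length-4 vector
#'   filled by row.
#' @param continuity_correction Apply the Yates correction? Default
#'   FALSE.
#' @return list(statistic, p_value, expected).
#' @export
chi_square_2x2 <- function(table, continuity_correction = FALSE) {
  if (!is.matrix(table)) {
    if (length(table) != 4) stop("table must be 2x2 (or a length-4 vector)")
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (!all(dim(table) == 2)) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal: chi-square undefined")
  ht <- suppressWarnings(
    stats::chisq.test(table, correct = continuity_correction))
  if (any(ht$expected <= 0)) stop("expected counts must all be > 0")
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       expected = ht$expected)
}

#' Upper-tail chi-square(1 df) probability for a reported statistic
#'
#' @param statistic Non-negative chi-square statistic.
#' @return P(X >= statistic) for X ~ chi-square with 1 df.
#' @export
chi_square_pvalue <- function(statistic) {
  stopifnot(statistic >= 0)
  stats::pchisq(statistic, df = 1, lower.tail = FALSE)
}

#' Maturation rate as a percentage
#'
#' @param matured Number of matured oocytes (0 <= matured <= total).
#' @param total Total oocytes (> 0).
#' @return 100 * matured / total.
#' @export
maturation_rate <- function(matured, total) {
  if (total <= 0) stop("total must be > 0")
  if (matured < 0 || matured > total)
    stop("matured must be between 0 and total")
  100 * matured / total
}
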