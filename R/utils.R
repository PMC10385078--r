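#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for reported percentages, as opposed
#' to [base::round()]'s round-half-even. Only sensible for non-negative input,
#' which is all this package reports.
#'
#' @param x numeric vector, non-negative.
#' @param digits integer, decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(76.5)   # 77, where round(76.5) gives 76
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# validate an internal counts matrix: samples as rows, ASVs as columns
validate_counts <- function(counts, require_positive_asvs = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix (samples x ASVs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have sample row names and ASV column names")
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0)) stopf("counts contain negative values")
  if (any(counts != trunc(counts))) stopf("counts contain non-integer values")
  if (anyDuplicated(rownames(counts))) stopf("duplicated sample ids in counts")
  if (anyDuplicated(colnames(counts))) stopf("duplicated ASV ids in counts")
  if (require_positive_asvs && ncol(counts) > 0 && any(colSums(counts) < 1))
    stopf("every ASV must have total count >= 1")
  invisible(counts)
}
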