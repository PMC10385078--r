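#' Match mock-sample ASVs to the expected species
#'
#' Each ASV of a mock-community sample is matched to the expected species
#' with minimum global edit distance, provided that distance does not
#' exceed `max_mismatch` (one base mismatch by default, so 1-mismatch
#' sequencing-error variants still count as "assigned" to a species).
#' Among tied species the lexicographically smallest species id wins.
#'
#' @param mock_counts a one-sample counts matrix (1 x ASVs).
#' @param mock_seqs [seq_records()] of the mock sample's ASVs.
#' @param expected [seq_records()] of the expected species sequences.
#' @param max_mismatch maximum edit distance still counted as a match.
#' @return data frame of class `mock_match` with columns `asv`,
#'   `matched_species` (`NA` if unmatched), `edit_distance`, `reads`,
#'   `proportion`; attributes `total_reads` and `n_expected`.
#' @export
match_mock <- function(mock_counts, mock_seqs, expected, max_mismatch = 1) {
  if (nrow(mock_counts) != 1)
    stopf("mock_counts must contain exactly one sample, got %d",
          nrow(mock_counts))
  asvs <- colnames(mock_counts)
  seqs <- mock_seqs$seq[match(asvs, mock_seqs$id)]
  if (anyNA(seqs)) stopf("missing sequence for mock ASV %s",
                         asvs[is.na(seqs)][1])
  ord <- order(expected$id)
  expected <- expected[ord, , drop = FALSE]
  ed <- .edit_distance_matrix_c(seqs, expected$seq)
  best <- apply(ed, 1, which.min)  # first min = smallest species id
  dmin <- ed[cbind(seq_along(asvs), best)]
  matched <- dmin <= max_mismatch
  reads <- as.vector(mock_counts[1, ])
  total <- sum(reads)
  out <- data.frame(
    asv = asvs,
    matched_species = ifelse(matched, expected$id[best], NA_character_),
    edit_distance = dmin,
    reads = reads,
    proportion = reads / total,
    stringsAsFactors = FALSE
  )
  attr(out, "total_reads") <- total
  attr(out, "n_expected") <- nrow(expected)
  class(out) <- c("mock_match", "data.frame")
  out
}

#' Lenient per-library threshold from a mock sample
#'
#' The read proportion of the matched ASV with the smallest read count —
#' the proportion of reads in the ASV with the fewest reads still assigned
#' to one of the expected species (allowing `max_mismatch`). Applied with
#' keep-if-`>=` semantics, so the defining ASV itself survives filtering at
#' its own threshold.
#'
#' @param match a [match_mock()] result.
#' @return the threshold as a proportion in `[0, 1]`.
#' @export
lenient_threshold <- function(match) {
  m <- match[!is.na(match$matched_species), , drop = FALSE]
  if (nrow(m) == 0)
    stopf("no mock ASV matched an expected species; mock failed")
  min(m$reads) / attr(match, "total_reads")
}

#' Strict per-library threshold from a mock sample
#'
#' The minimum read proportion necessary for the filtered mock to contain
#' only the expected ASVs (the distance-0 ASV of each species; 1-mismatch
#' variants are noise here, not expected). Reported as an exclusive bound:
#' the largest proportion among non-expected ASVs, applied with
#' keep-if-`>` semantics. The bound is feasible when every expected ASV's
#' proportion strictly exceeds it, i.e. filtering the mock at the bound
#' returns exactly the expected set.
#'
#' @param match a [match_mock()] result.
#' @return list with `t_strict`, `feasible`, and `diagnostics` (defining
#'   ASV ids and proportions).
#' @export
strict_threshold <- function(match) {
  is_exp <- !is.na(match$matched_species) & match$edit_distance == 0
  n_species <- length(unique(match$matched_species[is_exp]))
  if (n_species < attr(match, "n_expected"))
    stopf("only %d of %d expected species have a distance-0 ASV; mock incomplete",
          n_species, attr(match, "n_expected"))
  non_exp <- match[!is_exp, , drop = FALSE]
  t_strict <- if (nrow(non_exp)) max(non_exp$proportion) else 0
  feasible <- all(match$proportion[is_exp] > t_strict)
  def <- if (nrow(non_exp))
    non_exp$asv[which.max(non_exp$proportion)] else NA_character_
  list(t_strict = t_strict, feasible = feasible,
       diagnostics = list(defining_asv = def,
                          min_expected = min(match$proportion[is_exp])))
}

#' Calibrate per-library thresholds from a set of mock libraries
#'
#' Runs [match_mock()], [lenient_threshold()] and [strict_threshold()] on
#' one mock library per sequencing library and collects the results into a
#' threshold table consumed by [apply_threshold()].
#'
#' @param mocks named list (by library id) of mock libraries, each a list
#'   with `counts` and `seqs` (as produced by [generate_mock_library()]).
#' @param expected [seq_records()] of expected species, a named list of
#'   such (one per library), or `NULL` to take each mock's own design.
#' @param max_mismatch passed to [match_mock()].
#' @return data frame of class `threshold_set` with columns `library_id`,
#'   `t_lenient`, `t_strict`, `feasible_strict`.
#' @export
calibrate_thresholds <- function(mocks, expected = NULL, max_mismatch = 1) {
  per_lib <- lapply(names(mocks), function(lib) {
    exp_lib <- if (is.null(expected)) mocks[[lib]]$design$expected
               else if (is.data.frame(expected)) expected
               else expected[[lib]]
    mm <- match_mock(mocks[[lib]]$counts, mocks[[lib]]$seqs, exp_lib,
                     max_mismatch)
    st <- strict_threshold(mm)
    data.frame(library_id = lib, t_lenient = lenient_threshold(mm),
               t_strict = st$t_strict, feasible_strict = st$feasible,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_lib)
  class(out) <- c("threshold_set", "data.frame")
  out
}

threshold_for <- function(thresholds, lib, mode) {
  i <- match(lib, thresholds$library_id)
  if (is.na(i)) stopf("no threshold calibrated for library %s", lib)
  if (mode == "lenient") thresholds$t_lenient[i] else thresholds$t_strict[i]
}

#' Apply per-library read-proportion thresholds to a count table
#'
#' Filters each environmental sample with the threshold of its own
#' sequencing library. Proportions are computed against the sample's total
#' reads before filtering. Lenient mode keeps an ASV when its proportion is
#' `>=` the lenient threshold (ASVs with less than the threshold proportion
#' are filtered out); strict mode keeps when the proportion is strictly `>`
#' the strict bound. ASVs left with zero reads in every sample are dropped.
#'
#' @param env counts matrix, samples x ASVs (environmental samples only).
#' @param meta metadata with `sample` and `library_id`.
#' @param thresholds a [calibrate_thresholds()] table.
#' @param mode `"lenient"` or `"strict"`.
#' @return filtered counts matrix with a `removal_log` attribute (per
#'   sample: ASVs and reads removed).
#' @export
apply_threshold <- function(env, meta, thresholds,
                            mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  validate_counts(env)
  libs <- meta$library_id[match(rownames(env), meta$sample)]
  if (anyNA(libs)) stopf("sample %s missing from metadata",
                         rownames(env)[is.na(libs)][1])
  out <- env
  log <- vector("list", nrow(env))
  names(log) <- rownames(env)
  for (s in seq_len(nrow(env))) {
    t_s <- threshold_for(thresholds, libs[s], mode)
    prop <- env[s, ] / sum(env[s, ])
    keep <- if (mode == "lenient") prop >= t_s else prop > t_s
    removed <- !keep & env[s, ] > 0
    out[s, !keep] <- 0L
    log[[s]] <- list(threshold = t_s, n_removed = sum(removed),
                     reads_removed = sum(env[s, removed]))
  }
  out <- out[, colSums(out) > 0, drop = FALSE]
  attr(out, "removal_log") <- log
  out
}

#' Partition an environmental table into main, strict and low-abundance sets
#'
#' The three derived datasets of the calibration procedure: `main` applies
#' the lenient per-library threshold; `strict` applies the strict bound;
#' `low_abundant` collects exactly the cells removed by the lenient filter,
#' restricted to ASVs whose best reference identity is strictly greater
#' than `low_identity_min` (removing "noisy" low-abundance ASVs). By
#' construction a given ASV's reads in a given sample land in `main` or in
#' the low-abundance candidate set, never both.
#'
#' @param env counts matrix, samples x ASVs, already restricted to
#'   heterotroph ASVs (see [filter_functional()]).
#' @param meta metadata with `sample` and `library_id`.
#' @param thresholds a [calibrate_thresholds()] table.
#' @param assign an [assign_all()] table covering the ASVs of `env`.
#' @param low_identity_min identity cutoff (percent, strict `>`) for the
#'   low-abundance dataset.
#' @return list of class `dataset_partition` with counts matrices `main`,
#'   `strict`, `low_abundant` and a `provenance` summary.
#' @export
partition_datasets <- function(env, meta, thresholds, assign,
                               low_identity_min = 98) {
  main <- apply_threshold(env, meta, thresholds, "lenient")
  strict <- apply_threshold(env, meta, thresholds, "strict")
  low <- env
  low[, colnames(main)] <- low[, colnames(main)] - main[, colnames(main)]
  # cells removed by the lenient filter; keep only high-identity ASVs
  ident <- assign$identity_pct[match(colnames(low), assign$asv)]
  if (anyNA(ident)) stopf("ASV %s missing from assignment table",
                          colnames(low)[is.na(ident)][1])
  low[, !(ident > low_identity_min)] <- 0L
  low <- low[, colSums(low) > 0, drop = FALSE]
  out <- list(main = main, strict = strict, low_abundant = low,
              provenance = list(
                lenient = attr(main, "removal_log"),
                strict = attr(strict, "removal_log"),
                low_identity_min = low_identity_min))
  class(out) <- "dataset_partition"
  out
}

#' @export
print.dataset_partition <- function(x, ...) {
  cat("Dataset partition\n")
  for (nm in c("main", "strict", "low_abundant"))
    cat(sprintf("  %-12s %4d ASVs, %d samples, %d reads\n", nm,
                ncol(x[[nm]]), nrow(x[[nm]]), sum(x[[nm]])))
  invisible(x)
}
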