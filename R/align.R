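#' Unit-cost global pairwise alignment
#'
#' End-to-end (Needleman-Wunsch) alignment under unit costs: match 0,
#' mismatch 1, gap 1. `edits` is the global edit distance; `aln_len` is the
#' number of columns of the edit-optimal alignment with the fewest gap
#' columns, which makes the reported alignment length deterministic.
#' Percent identity is `100 * (aln_len - edits) / aln_len`, the definition
#' applied to the `>80%` assignment and `>98%` low-abundance cutoffs.
#'
#' @param a,b non-empty nucleotide strings (normalised internally as in
#'   [seq_records()]).
#' @return list with `edits`, `aln_len`, `identity_pct`.
#' @export
#' @examples
#' global_align("ACGT", "ACGA")$identity_pct   # 75
#' global_align("ACGT", "ACGTT")$identity_pct  # 80
global_align <- function(a, b) {
  a <- chartr("U", "T", toupper(a)); b <- chartr("U", "T", toupper(b))
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  if (!grepl("^[ACGTN]+$", a) || !grepl("^[ACGTN]+$", b))
    stopf("sequences must be over A,C,G,T,U,N")
  r <- .edit_align_c(a, b)
  list(edits = unname(r[["edits"]]), aln_len = unname(r[["aln_len"]]),
       identity_pct = 100 * (r[["aln_len"]] - r[["edits"]]) / r[["aln_len"]])
}

#' Assign ASVs to a reference database by best global-alignment identity
#'
#' Every query is aligned against every reference; the best hit is the
#' reference with maximum percent identity (ties broken by the
#' lexicographically smallest reference id, so the result does not depend
#' on reference order). An assignment is retained only when identity is
#' strictly greater than `min_identity`; otherwise the ASV is recorded as
#' unassigned (its best observed identity is still reported).
#'
#' @param queries [seq_records()] of ASV sequences.
#' @param refs [seq_records()] of reference sequences; `lineage` required.
#' @param min_identity assignment cutoff in percent (strict `>`).
#' @param config functional classification map, see [exclusion_config()].
#' @return data frame of class `assignment_table` with columns `asv`,
#'   `best_ref`, `identity_pct`, `lineage`, `division`, `functional_class`.
#' @export
assign_all <- function(queries, refs, min_identity = 80,
                       config = exclusion_config()) {
  if (nrow(refs) == 0) stopf("reference set is empty")
  if (anyNA(refs$lineage)) stopf("all reference sequences need a lineage")
  ord <- order(refs$id)
  refs <- refs[ord, , drop = FALSE]
  idm <- .identity_matrix_c(queries$seq, refs$seq)
  best <- apply(idm, 1, which.max)  # first max = smallest ref id after sort
  best_id <- refs$id[best]
  ident <- idm[cbind(seq_len(nrow(queries)), best)]
  assigned <- ident > min_identity
  lin <- ifelse(assigned, refs$lineage[best], NA_character_)
  out <- data.frame(
    asv = queries$id,
    best_ref = ifelse(assigned, best_id, NA_character_),
    identity_pct = ident,
    lineage = lin,
    division = lineage_division(lin),
    functional_class = functional_class(lin, config),
    stringsAsFactors = FALSE
  )
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Restrict an assignment table to heterotrophic protist ASVs
#'
#' Drops ASVs that could not be assigned above the identity cutoff and
#' ASVs classified as metazoa, fungi, streptophytes or exclusively
#' phototrophic taxa.
#'
#' @param assign an [assign_all()] table.
#' @return character vector of retained ASV ids.
#' @export
filter_functional <- function(assign) {
  assign$asv[!is.na(assign$best_ref) &
               assign$functional_class == "heterotroph"]
}

#' Search a count table for a genotype at 100% identity
#'
#' Used to ask whether the V9 genotype of a cultivated strain occurs in
#' the metabarcoding dataset: sums reads over all ASVs whose global
#' pairwise identity to the target sequence is exactly 100%.
#'
#' @param asv_seqs [seq_records()] of the ASVs in `counts`.
#' @param counts integer matrix, samples x ASVs.
#' @param target a single target sequence (character string or one-row
#'   [seq_records()]).
#' @return named numeric vector of total reads per sample in which the
#'   genotype occurs; empty when no ASV is identical to the target.
#' @export
find_genotype <- function(asv_seqs, counts, target) {
  if (is.data.frame(target)) target <- target$seq[1]
  target <- chartr("U", "T", toupper(target))
  if (!nzchar(target)) stopf("target sequence must be non-empty")
  idm <- .identity_matrix_c(asv_seqs$seq, target)
  hit <- asv_seqs$id[idm[, 1] == 100]
  hit <- intersect(hit, colnames(counts))
  if (length(hit) == 0) return(stats::setNames(numeric(0), character(0)))
  tot <- rowSums(counts[, hit, drop = FALSE])
  tot[tot > 0]
}
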