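#' Construct a set of sequence records
#'
#' The basic container for ASV, mock-reference and database sequences: a
#' data frame with columns `id`, `seq` and (optionally) a PR2-style
#' semicolon-separated `lineage` string. Sequences are upper-cased and RNA
#' `U` is mapped to `T` so that all downstream alignment operates on a
#' single DNA alphabet.
#'
#' @param id character vector of unique identifiers (no whitespace).
#' @param seq character vector of nucleotide sequences over `A,C,G,T,U,N`
#'   (case-insensitive).
#' @param lineage optional character vector of lineage strings (`NA` where
#'   absent).
#' @return a data frame of class `seq_records` with columns `id`, `seq`,
#'   `lineage`.
#' @export
seq_records <- function(id, seq, lineage = NA_character_) {
  id <- as.character(id)
  seq <- chartr("U", "T", toupper(as.character(seq)))
  lineage <- rep_len(as.character(lineage), length(id))
  if (length(id) != length(seq)) stopf("id and seq lengths differ")
  if (any(!nzchar(id)) || any(grepl("\\s", id)))
    stopf("sequence ids must be non-empty and contain no whitespace")
  dup <- id[duplicated(id)]
  if (length(dup)) stopf("duplicate sequence id: %s", dup[1])
  if (any(!nzchar(seq))) stopf("empty sequence for id %s", id[!nzchar(seq)][1])
  bad <- !grepl("^[ACGTN]+$", seq)
  if (any(bad))
    stopf("sequence %s contains characters outside A,C,G,T,U,N", id[bad][1])
  out <- data.frame(id = id, seq = seq, lineage = lineage,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read sequences from a FASTA file
#'
#' Headers are split at the first whitespace: the first token is the record
#' id, any remainder is kept as the lineage string (the convention used for
#' the package's PR2-style reference files).
#'
#' @param path path to a FASTA file.
#' @return a [seq_records()] data frame, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stopf("no sequences in %s", path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  lineage <- ifelse(grepl("\\s", headers),
                    sub("^\\S+\\s+", "", headers), NA_character_)
  seq_records(id, as.character(x), lineage)
}

#' Write sequence records to FASTA
#'
#' @param records a [seq_records()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(is.na(records$lineage), records$id,
                paste(records$id, records$lineage))
  writeLines(paste0(">", hdr, "\n", records$seq, collapse = "\n"), path)
  invisible(path)
}

#' Read an ASV count table
#'
#' Reads a TSV count table into the package's internal orientation
#' (samples as rows, ASVs as columns, the `vegan` convention). The default
#' file layout has ASVs as rows and samples as columns, matching common
#' dada2 exports; set `asvs_as = "columns"` for transposed files.
#'
#' @param path path to a TSV file; first column holds ids, remaining
#'   columns are integer counts.
#' @param asvs_as `"rows"` (default) if file rows are ASVs, `"columns"` if
#'   file rows are samples.
#' @return integer matrix, samples x ASVs.
#' @export
read_count_table <- function(path, asvs_as = c("rows", "columns")) {
  asvs_as <- match.arg(asvs_as)
  if (!file.exists(path)) stopf("file not found: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    stopf("ragged count table: rows with differing field counts in %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stopf("count table needs an id column plus counts")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stopf("duplicate row id in count table: %s",
                                ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | num < 0 | num != trunc(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("invalid count '%s' at row '%s', column '%s'",
          m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
  storage.mode(num) <- "integer"
  rownames(num) <- ids
  colnames(num) <- colnames(m)
  counts <- if (asvs_as == "rows") t(num) else num
  validate_counts(counts)
  counts
}

#' Write an ASV count table to TSV
#'
#' @param counts integer matrix, samples x ASVs (internal orientation).
#' @param path output path.
#' @param asvs_as `"rows"` (default) writes ASVs as file rows.
#' @param id_column header for the id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, asvs_as = c("rows", "columns"),
                              id_column = "asv") {
  asvs_as <- match.arg(asvs_as)
  m <- if (asvs_as == "rows") t(counts) else counts
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- if (asvs_as == "rows") id_column else "sample"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a PR2-style lineage string
#'
#' PR2 lineages carry eight ranks (kingdom to species) separated by
#' semicolons; the third rank is the division, the level used for
#' taxonomic-composition profiles. Strings with fewer ranks are padded with
#' the placeholder token `"unassigned"`.
#'
#' @param s a single lineage string, ranks separated by `";"`.
#' @return list with `ranks` (character of length 8) and `division`.
#' @export
#' @examples
#' parse_lineage("Eukaryota;Alveolata;Dinoflagellata;Dinophyceae")$division
parse_lineage <- function(s) {
  if (length(s) != 1 || is.na(s) || !nzchar(trimws(s)))
    stopf("empty lineage string")
  ranks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  if (length(ranks) > 8) stopf("lineage has more than 8 ranks: %s", s)
  ranks[!nzchar(ranks)] <- "unassigned"
  ranks <- c(ranks, rep("unassigned", 8 - length(ranks)))
  list(ranks = ranks, division = ranks[3])
}

#' Extract divisions from lineage strings
#'
#' @param lineages character vector of lineage strings (`NA` allowed).
#' @return character vector of divisions (`NA` where lineage missing).
#' @export
lineage_division <- function(lineages) {
  vapply(lineages, function(s) {
    if (is.na(s)) NA_character_ else parse_lineage(s)$division
  }, character(1), USE.NAMES = FALSE)
}

#' Read and validate sample metadata
#'
#' Expects a TSV with columns `sample`, `island`, `depth_m`, `transect`,
#' `library_id`, `sample_role`. Each environmental sample must belong to a
#' sequencing library that also carries exactly one mock-community sample,
#' since per-library filtering thresholds are calibrated from that mock.
#'
#' @param path path to the metadata TSV.
#' @param depth_strata numeric vector of admissible sampling depths (m) for
#'   environmental samples.
#' @return a validated data frame of per-sample metadata.
#' @export
read_metadata <- function(path,
                          depth_strata = c(50, 150, 300, 500, 1000, 1500, 2000)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df, depth_strata)
}

#' @rdname read_metadata
#' @param meta an in-memory metadata data frame to validate.
#' @export
validate_metadata <- function(meta,
                              depth_strata = c(50, 150, 300, 500, 1000, 1500, 2000)) {
  need <- c("sample", "island", "depth_m", "transect", "library_id",
            "sample_role")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("metadata missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample))
    stopf("duplicate sample id: %s", meta$sample[duplicated(meta$sample)][1])
  bad_role <- setdiff(unique(meta$sample_role), c("environmental", "mock"))
  if (length(bad_role)) stopf("unknown sample_role: %s", bad_role[1])
  env <- meta[meta$sample_role == "environmental", , drop = FALSE]
  mock <- meta[meta$sample_role == "mock", , drop = FALSE]
  off <- !env$depth_m %in% depth_strata
  if (any(off))
    stopf("sample %s has depth_m %s outside the declared strata",
          env$sample[off][1], env$depth_m[off][1])
  n_mock <- table(mock$library_id)
  orphan <- setdiff(unique(env$library_id), names(n_mock))
  if (length(orphan))
    stopf("environmental library %s has no mock-community sample", orphan[1])
  multi <- names(n_mock)[n_mock > 1]
  if (length(multi))
    stopf("library %s has more than one mock-community sample", multi[1])
  meta
}

#' Write sample metadata to TSV
#'
#' @param meta metadata data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
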