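#' Per-group ASV presence
#'
#' Maps every ASV to the set of sample groups in which it occurs with at
#' least one read in at least one sample. Groups are defined by a named
#' mapping from a metadata key (depth in metres, or island) to group
#' labels, e.g. [depth_sharing_grouping()] for the five-way depth grouping
#' or an identity map over islands.
#'
#' @param counts counts matrix, samples x ASVs.
#' @param meta metadata with `sample` and the grouping key.
#' @param key `"depth_m"` or `"island"`.
#' @param grouping named character vector mapping key values (as
#'   character) to group labels; `NULL` uses each key value as its own
#'   group.
#' @return list of class `group_presence` with `groups` (ordered labels)
#'   and `membership` (named list: ASV -> character vector of groups).
#' @export
group_presence <- function(counts, meta, key = c("depth_m", "island"),
                           grouping = NULL) {
  key <- match.arg(key)
  val <- as.character(meta[[key]][match(rownames(counts), meta$sample)])
  if (anyNA(val)) stopf("sample %s missing from metadata",
                        rownames(counts)[is.na(val)][1])
  if (is.null(grouping)) {
    u <- sort(unique(val))
    grouping <- stats::setNames(u, u)
  }
  if (any(!val %in% names(grouping)))
    stopf("sample %s has %s value '%s' not covered by the grouping",
          rownames(counts)[!val %in% names(grouping)][1], key,
          val[!val %in% names(grouping)][1])
  grp <- unname(grouping[val])
  groups <- unique(unname(grouping))
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warnf("%d ASV(s) with zero reads excluded from presence accounting",
          sum(empty))
    counts <- counts[, !empty, drop = FALSE]
  }
  membership <- lapply(seq_len(ncol(counts)), function(a) {
    g <- unique(grp[counts[, a] > 0])
    groups[groups %in% g]
  })
  names(membership) <- colnames(counts)
  structure(list(groups = groups, membership = membership),
            class = "group_presence")
}

#' Exact intersection (UpSet) report of shared and unique ASVs
#'
#' Counts ASVs per exact group combination (each ASV falls in exactly one
#' cell, UpSet semantics, not cumulative Venn counts), plus per-group
#' totals, per-group unique counts and the shared-by-all count.
#' Percentages use a declared denominator (by default the total number of
#' ASVs counted) and are reported raw and rounded half-up to integers.
#'
#' @param gp a [group_presence()] object.
#' @param denominator percentage denominator; must be at least the number
#'   of ASVs counted.
#' @return list of class `intersection_report` with `combinations` (data
#'   frame: `combination`, `degree`, `n`, `pct`, `pct_rounded`),
#'   `group_totals`, `unique_counts`, `shared_all`, `unique_total`,
#'   `unique_pct_rounded`, `shared_all_pct_rounded`, `denominator`.
#' @export
intersections <- function(gp, denominator = NULL) {
  n_asv <- length(gp$membership)
  denominator <- denominator %||% n_asv
  if (denominator < n_asv)
    stopf("denominator %d smaller than the %d ASVs counted",
          denominator, n_asv)
  key <- vapply(gp$membership, paste, character(1), collapse = "&")
  tab <- table(key)
  deg <- vapply(strsplit(names(tab), "&", fixed = TRUE), length, integer(1))
  ord <- order(-as.integer(tab))
  combos <- data.frame(combination = names(tab)[ord],
                       degree = deg[ord],
                       n = as.integer(tab)[ord],
                       stringsAsFactors = FALSE)
  combos$pct <- 100 * combos$n / denominator
  combos$pct_rounded <- round_half_up(combos$pct)
  in_group <- function(g) vapply(gp$membership, function(m) g %in% m,
                                 logical(1))
  group_totals <- vapply(gp$groups, function(g) sum(in_group(g)), integer(1))
  unique_counts <- vapply(gp$groups, function(g) {
    sum(vapply(gp$membership, function(m) identical(m, g), logical(1)))
  }, integer(1))
  shared_all <- sum(vapply(gp$membership, function(m)
    length(m) == length(gp$groups), logical(1)))
  unique_total <- sum(unique_counts)
  structure(list(
    combinations = combos,
    group_totals = group_totals,
    unique_counts = unique_counts,
    shared_all = shared_all,
    unique_total = unique_total,
    unique_pct = 100 * unique_total / denominator,
    unique_pct_rounded = round_half_up(100 * unique_total / denominator),
    shared_all_pct = 100 * shared_all / denominator,
    shared_all_pct_rounded = round_half_up(100 * shared_all / denominator),
    denominator = denominator, n_asv = n_asv),
    class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("ASV intersections over %d groups (%d ASVs, denominator %d)\n",
              length(x$group_totals), x$n_asv, x$denominator))
  cat(sprintf("  unique to a single group: %d (%d%%)\n",
              x$unique_total, x$unique_pct_rounded))
  cat(sprintf("  shared by all groups:     %d (%d%%)\n",
              x$shared_all, x$shared_all_pct_rounded))
  print(utils::head(x$combinations, 10), row.names = FALSE)
  invisible(x)
}

#' Taxonomic profile of unique or shared-by-all ASVs
#'
#' Division-level [taxon_profile()] of the ASVs unique to a single group,
#' or of those shared between all groups.
#'
#' @param gp a [group_presence()] object.
#' @param assign an [assign_all()] table.
#' @param which `"unique"` or `"shared_all"`.
#' @param min_prop lumping threshold passed to [taxon_profile()].
#' @return data frame with `division` and `proportion`.
#' @export
unique_shared_taxa <- function(gp, assign, which = c("unique", "shared_all"),
                               min_prop = 0.02) {
  which <- match.arg(which)
  sel <- vapply(gp$membership, function(m) {
    if (which == "unique") length(m) == 1 else length(m) == length(gp$groups)
  }, logical(1))
  ids <- names(gp$membership)[sel]
  if (length(ids) == 0) stopf("no ASVs in the '%s' subset", which)
  taxon_profile(ids, assign, min_prop)
}
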