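#' Shannon diversity index
#'
#' `H = -sum(p_i log p_i)` over ASVs with positive counts; natural
#' logarithm by default (the vegan convention), configurable base.
#'
#' @param counts non-negative numeric vector of reads per ASV.
#' @param base logarithm base.
#' @return the Shannon index.
#' @export
#' @examples
#' shannon(c(10, 10, 10, 10))  # log(4)
shannon <- function(counts, base = exp(1)) {
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be non-negative")
  if (sum(counts) == 0) stopf("all counts are zero")
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Analytic rarefaction curve
#'
#' Expected ASV richness in random subsamples of `depth` reads drawn
#' without replacement:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`. Deterministic
#' (hypergeometric) rather than resampling-based; computed with
#' [vegan::rarefy()].
#'
#' @param counts non-negative integer vector of reads per ASV.
#' @param depths increasing integer subsample sizes, each `<=` the total.
#' @return data frame with `depth` and `expected_richness`.
#' @export
rarefaction <- function(counts, depths) {
  total <- sum(counts)
  if (any(depths > total))
    stopf("rarefaction depth %d exceeds the sample total %d",
          max(depths), total)
  if (any(depths < 1)) stopf("rarefaction depths must be >= 1")
  # vegan::rarefy emits a data-shape advisory when the smallest count
  # exceeds 1; it has no bearing on the expectation computed here
  er <- vapply(depths, function(n) {
    withCallingHandlers(
      as.numeric(vegan::rarefy(counts, sample = n)),
      warning = function(w) {
        if (grepl("smallest count", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }, numeric(1))
  data.frame(depth = as.integer(depths), expected_richness = er)
}

#' Per-group richness and read-total summaries
#'
#' Mean and sample standard deviation (n-1 denominator) of per-sample ASV
#' richness (ASVs with at least one read) and of per-sample read totals,
#' grouped by a metadata key. Single-sample groups report `sd = 0` and are
#' flagged by `n = 1`.
#'
#' @param counts counts matrix, samples x ASVs.
#' @param meta metadata with a `sample` column and the grouping key.
#' @param key grouping column, e.g. `"depth_m"` or `"island"`.
#' @return data frame with per-group `n`, `mean_richness`, `sd_richness`,
#'   `mean_reads`, `sd_reads`.
#' @export
group_summary <- function(counts, meta, key = c("depth_m", "island")) {
  key <- match.arg(key)
  grp <- meta[[key]][match(rownames(counts), meta$sample)]
  if (anyNA(grp)) stopf("sample %s missing from metadata",
                        rownames(counts)[is.na(grp)][1])
  rich <- rowSums(counts > 0)
  reads <- rowSums(counts)
  levs <- unique(grp)
  rows <- lapply(levs, function(g) {
    i <- grp == g
    if (!any(i)) return(NULL)
    data.frame(group = g, n = sum(i),
               mean_richness = mean(rich[i]),
               sd_richness = if (sum(i) > 1) sd(rich[i]) else 0,
               mean_reads = mean(reads[i]),
               sd_reads = if (sum(i) > 1) sd(reads[i]) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Division-level taxonomic composition profile
#'
#' Relative proportions of ASVs per PR2 division over a chosen ASV set,
#' with divisions below `min_prop` of the set cumulated into `"Others"`.
#'
#' @param asv_ids character vector of ASV ids.
#' @param assign an [assign_all()] table covering those ASVs.
#' @param min_prop divisions below this proportion are lumped (default 2%).
#' @return data frame with `division` and `proportion`, proportions
#'   summing to 1.
#' @export
taxon_profile <- function(asv_ids, assign, min_prop = 0.02) {
  if (length(asv_ids) == 0) stopf("empty ASV set")
  div <- assign$division[match(asv_ids, assign$asv)]
  if (anyNA(div)) stopf("ASV %s has no assigned division",
                        asv_ids[is.na(div)][1])
  tab <- table(div) / length(div)
  small <- tab < min_prop
  prop <- c(sort(tab[!small], decreasing = TRUE),
            if (any(small)) c(Others = sum(tab[small])))
  data.frame(division = names(prop), proportion = as.numeric(prop),
             stringsAsFactors = FALSE)
}

#' Pipeline read-accounting report
#'
#' Summarises how many reads survive each stage of the pipeline: mean raw
#' reads per sample (reported in millions to one decimal), the percentage
#' of quality-filtered reads assigned to a reference above the identity
#' cutoff, and the percentage of assigned reads associated with
#' heterotrophic protists. Percentages are reported raw and rounded half-up
#' to the nearest integer.
#'
#' @param raw_total total raw demultiplexed reads.
#' @param n_samples number of samples.
#' @param assigned_total reads assigned above the identity cutoff.
#' @param filtered_total quality-filtered reads (assignment denominator).
#' @param heterotroph_total assigned reads from heterotrophic protists.
#' @return list with `mean_reads_per_sample`, `mean_reads_million`,
#'   `assigned_pct` / `assigned_pct_rounded`, `heterotroph_pct` /
#'   `heterotroph_pct_rounded`.
#' @export
pipeline_report <- function(raw_total, n_samples, assigned_total,
                            filtered_total, heterotroph_total) {
  vals <- c(raw_total, n_samples, assigned_total, filtered_total,
            heterotroph_total)
  if (anyNA(vals) || any(vals < 0)) stopf("totals must be non-negative")
  if (n_samples == 0 || filtered_total == 0 || assigned_total == 0)
    stopf("zero denominator in pipeline report")
  if (assigned_total > filtered_total || heterotroph_total > assigned_total)
    stopf("nested totals exceed their denominators")
  mean_reads <- raw_total / n_samples
  assigned_pct <- 100 * assigned_total / filtered_total
  het_pct <- 100 * heterotroph_total / assigned_total
  list(mean_reads_per_sample = mean_reads,
       mean_reads_million = round_half_up(mean_reads / 1e6, 1),
       assigned_pct = assigned_pct,
       assigned_pct_rounded = round_half_up(assigned_pct),
       heterotroph_pct = het_pct,
       heterotroph_pct_rounded = round_half_up(het_pct))
}
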