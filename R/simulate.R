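random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute exactly n_sub positions (each to a different base)
mutate_substitutions <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

division_supergroup <- c(
  Dinoflagellata = "Alveolata", Ciliophora = "Alveolata",
  Apicomplexa = "Alveolata",
  Radiolaria = "Rhizaria", Cercozoa = "Rhizaria", Foraminifera = "Rhizaria",
  Discicristata = "Discoba", Stramenopiles = "Stramenopiles",
  Choanoflagellida = "Opisthokonta", Metazoa = "Opisthokonta",
  Fungi = "Opisthokonta",
  Streptophyta = "Archaeplastida", Chlorophyta = "Archaeplastida"
)

#' Generate a synthetic PR2-style reference database
#'
#' Produces mutually distinct random V9-length sequences carrying 8-rank
#' PR2-style lineages. Divisions cycle through the major heterotrophic
#' protist groups of the study system plus the excluded groups (metazoans,
#' fungi, streptophytes, a phototroph division), so functional filtering is
#' exercised. All pairwise identities are checked to be below 95%.
#'
#' @param n_taxa number of reference taxa.
#' @param seq_length sequence length in nt (V9-like, default 130).
#' @param seed integer RNG seed.
#' @param divisions character vector of divisions to cycle through.
#' @return a [seq_records()] data frame with lineages.
#' @export
generate_reference_db <- function(n_taxa, seq_length = 130, seed = 1,
                                  divisions = c("Dinoflagellata", "Ciliophora",
                                                "Radiolaria", "Discicristata",
                                                "Stramenopiles",
                                                "Choanoflagellida", "Cercozoa",
                                                "Foraminifera", "Metazoa",
                                                "Fungi", "Streptophyta",
                                                "Chlorophyta")) {
  if (n_taxa < 1) stopf("n_taxa must be >= 1")
  if (seq_length < 50) stopf("seq_length must be >= 50 for V9-like sequences")
  set.seed(seed)
  seqs <- character(n_taxa)
  for (i in seq_len(n_taxa)) {
    ok <- FALSE
    for (try in 1:50) {
      s <- random_seq(seq_length)
      if (i == 1 ||
          max(.identity_matrix_c(s, seqs[seq_len(i - 1)])) < 95) {
        seqs[i] <- s; ok <- TRUE; break
      }
    }
    if (!ok)
      stopf("cannot place %d mutually distinct taxa at length %d",
            n_taxa, seq_length)
  }
  div <- rep_len(divisions, n_taxa)
  lin <- vapply(seq_len(n_taxa), function(i) {
    d <- div[i]
    paste("Eukaryota", division_supergroup[[d]], d, paste0(d, "_X"),
          sprintf("Order_%03d", i), sprintf("Family_%03d", i),
          sprintf("Genus_%03d", i), sprintf("Genus_%03d_sp.", i), sep = ";")
  }, character(1))
  seq_records(sprintf("ref_%03d", seq_len(n_taxa)), seqs, lin)
}

#' Design a synthetic mock-community library
#'
#' Describes the denoised output of sequencing a known mix of protist
#' species: the expected species ASVs at designed read proportions, plus
#' two kinds of low-abundance noise, 1-mismatch error variants of expected
#' sequences and unrelated contaminants (edit distance >= 2 from every
#' expected sequence). The default design mirrors the study conditions the
#' calibration assumes: nine expected species sharing 98.5% of the reads
#' equally, one error variant at 0.5% and one contaminant at 1.0%, so the
#' designed lenient threshold is 0.5% and the designed strict bound 1.0%.
#'
#' @param expected [seq_records()] of the expected species sequences, or
#'   `NULL` to generate `n_expected` random distinct species.
#' @param n_expected number of expected species when `expected` is `NULL`.
#' @param expected_props read proportions of the expected species, or
#'   `NULL` for equal shares of whatever the noise proportions leave.
#' @param error_variant_props named proportions of 1-mismatch variants
#'   (parents assigned cyclically over the expected species).
#' @param contaminant_props named proportions of unrelated contaminants.
#' @param total_reads mock-sample sequencing depth.
#' @param seq_len sequence length when generating expected species.
#' @param sample_id id of the mock sample.
#' @param seed integer RNG seed.
#' @return list of class `mock_design`.
#' @export
mock_design <- function(expected = NULL, n_expected = 9,
                        expected_props = NULL,
                        error_variant_props = c(variant_1 = 0.005),
                        contaminant_props = c(contaminant_1 = 0.01),
                        total_reads = 1e5, seq_len = 130,
                        sample_id = "mock", seed = 1) {
  if (is.null(expected))
    expected <- generate_reference_db(n_expected, seq_len, seed = seed)
  n_expected <- nrow(expected)
  noise <- sum(error_variant_props) + sum(contaminant_props)
  if (is.null(expected_props))
    expected_props <- rep((1 - noise) / n_expected, n_expected)
  if (length(expected_props) != n_expected)
    stopf("expected_props must match the number of expected species")
  props <- c(expected_props, error_variant_props, contaminant_props)
  if (any(props <= 0)) stopf("all designed proportions must be > 0")
  if (sum(props) > 1 + 1e-12)
    stopf("designed proportions sum to %.4f > 1", sum(props))
  structure(list(expected = expected, expected_props = expected_props,
                 error_variant_props = error_variant_props,
                 contaminant_props = contaminant_props,
                 total_reads = total_reads, seq_len = seq_len,
                 sample_id = sample_id, seed = seed),
            class = "mock_design")
}

#' Generate one synthetic mock-community library
#'
#' Draws ASV read counts by a single multinomial over the designed
#' proportions (per-sample totals are fixed, because read proportions are
#' the unit the calibration thresholds act on). When the designed
#' proportions sum to less than 1 they are renormalised, and the
#' renormalised values are recorded as the ground truth. The ground truth
#' also records the designed lenient threshold (smallest designed
#' proportion among expected species and error variants) and the designed
#' strict bound (largest designed proportion among non-expected ASVs),
#' together with strict-filtering feasibility.
#'
#' @param design a [mock_design()].
#' @return list with `counts` (1 x ASVs integer matrix), `seqs`
#'   ([seq_records()]), and `truth` (designed thresholds, per-ASV roles and
#'   designed proportions).
#' @export
generate_mock_library <- function(design) {
  stopifnot(inherits(design, "mock_design"))
  set.seed(design$seed)
  exp_seqs <- design$expected
  n_exp <- nrow(exp_seqs)
  nv <- length(design$error_variant_props)
  nc <- length(design$contaminant_props)

  var_seq <- character(nv); var_parent <- character(nv)
  if (nv > 0) {
    parents <- rep_len(seq_len(n_exp), nv)
    for (i in seq_len(nv)) {
      var_parent[i] <- exp_seqs$id[parents[i]]
      var_seq[i] <- mutate_substitutions(exp_seqs$seq[parents[i]], 1)
    }
  }
  con_seq <- character(nc)
  if (nc > 0) {
    for (i in seq_len(nc)) {
      repeat {
        s <- random_seq(design$seq_len)
        if (min(.edit_distance_matrix_c(s, exp_seqs$seq)) >= 2) {
          con_seq[i] <- s; break
        }
      }
    }
  }

  ids <- c(sprintf("mock_asv_%02d", seq_len(n_exp + nv + nc)))
  role <- c(rep("expected", n_exp), rep("error_variant", nv),
            rep("contaminant", nc))
  seqs <- c(exp_seqs$seq, var_seq, con_seq)
  props <- c(design$expected_props, design$error_variant_props,
             design$contaminant_props)
  props <- props / sum(props)  # renormalise; recorded as truth below

  counts <- as.integer(rmultinom(1, design$total_reads, props))
  keep <- counts > 0
  m <- matrix(counts[keep], nrow = 1,
              dimnames = list(design$sample_id, ids[keep]))

  exp_idx <- role == "expected"
  lenient <- min(props[role %in% c("expected", "error_variant")])
  strict <- if (any(!exp_idx)) max(props[!exp_idx]) else 0
  truth <- list(
    designed_lenient = lenient,
    designed_strict = strict,
    feasible_strict = strict < min(props[exp_idx]),
    asv = data.frame(asv = ids, role = role, designed_prop = props,
                     parent = c(exp_seqs$id, var_parent,
                                rep(NA_character_, nc)),
                     sampled = keep, stringsAsFactors = FALSE)
  )
  list(counts = m, seqs = seq_records(ids[keep], seqs[keep]), truth = truth,
       design = design)
}

#' Design a synthetic island-by-depth environmental dataset
#'
#' Encodes the community structure the downstream statistics are meant to
#' detect: a core ASV pool shared by all samples, depth-zone-specific pools
#' (three bathymetric zones) and island-specific pools. Setting
#' `zone_size` and `island_size` to zero yields exchangeable samples (the
#' null model used for permutation-test calibration).
#'
#' @param islands island names (default the three study islands).
#' @param depth_strata sampled depths in metres.
#' @param depth_zones named map depth -> zone label, see
#'   [depth_zone_grouping()].
#' @param core_size,zone_size,island_size pool sizes (ASVs); `zone_size`
#'   and `island_size` apply per zone / per island.
#' @param occupancy probability that a pool ASV is actually present in a
#'   given member sample (presence noise).
#' @param sdlog log-normal abundance spread across ASVs.
#' @param reads_per_sample fixed sequencing depth per sample.
#' @param prop_excluded fraction of ASVs sourced from excluded divisions
#'   (metazoa, fungi, streptophytes, phototrophs).
#' @param band_mix proportions of ASVs whose identity to their source
#'   reference falls above 98% (`high`), between 80 and 98% (`mid`) or
#'   below 80% (`low`, unrelated sequence), exercising both identity
#'   cutoffs.
#' @param n_libraries number of sequencing libraries samples are spread
#'   over (each carries one mock community).
#' @param seed integer RNG seed.
#' @return list of class `env_design`.
#' @export
env_design <- function(islands = c("Flores", "Terceira", "SantaMaria"),
                       depth_strata = c(50, 150, 300, 500, 1000, 1500, 2000),
                       depth_zones = depth_zone_grouping(),
                       core_size = 40, zone_size = 25, island_size = 20,
                       occupancy = 0.9, sdlog = 1, reads_per_sample = 1e5,
                       prop_excluded = 0.15,
                       band_mix = c(high = 0.7, mid = 0.2, low = 0.1),
                       n_libraries = 5, seed = 1) {
  zones <- unique(unname(depth_zones[as.character(depth_strata)]))
  if (anyNA(zones)) stopf("every depth stratum needs a zone label")
  if (core_size + zone_size + island_size <= 0)
    stopf("all pool sizes are zero; nothing to simulate")
  structure(list(islands = islands, depth_strata = depth_strata,
                 depth_zones = depth_zones, zones = zones,
                 core_size = core_size, zone_size = zone_size,
                 island_size = island_size, occupancy = occupancy,
                 sdlog = sdlog, reads_per_sample = reads_per_sample,
                 prop_excluded = prop_excluded,
                 band_mix = band_mix / sum(band_mix),
                 n_libraries = n_libraries, seed = seed),
            class = "env_design")
}

#' Generate a synthetic environmental ASV dataset
#'
#' Builds the ASV pools of an [env_design()], derives each ASV's sequence
#' from a reference-database entry (exact, lightly mutated to >98%
#' identity, mutated into the 80-98% band, or replaced by an unrelated
#' sequence below 80%), assembles per-sample communities from the pools
#' consistent with each sample's island and depth zone, and draws read
#' counts by multinomial sampling at fixed depth.
#'
#' @param design an [env_design()].
#' @param ref_db reference database ([generate_reference_db()] output);
#'   generated from the design seed when `NULL`.
#' @return list with `counts` (samples x ASVs), `seqs`, `metadata`,
#'   `truth` (per-ASV pool membership, source reference, identity band,
#'   functional class; per-sample designed community) and `ref_db`.
#' @export
generate_env_dataset <- function(design, ref_db = NULL) {
  stopifnot(inherits(design, "env_design"))
  set.seed(design$seed)
  if (is.null(ref_db))
    ref_db <- generate_reference_db(60, seed = design$seed)
  ref_class <- functional_class(ref_db$lineage)
  het_refs <- which(ref_class == "heterotroph")
  exc_refs <- which(ref_class != "heterotroph")

  pools <- c("core" = design$core_size,
             stats::setNames(rep(design$zone_size, length(design$zones)),
                             paste0("zone:", design$zones)),
             stats::setNames(rep(design$island_size, length(design$islands)),
                             paste0("island:", design$islands)))
  pools <- pools[pools > 0]
  n_asv <- sum(pools)
  pool_of <- rep(names(pools), pools)

  band <- sample(names(design$band_mix), n_asv, replace = TRUE,
                 prob = design$band_mix)
  excluded <- runif(n_asv) < design$prop_excluded
  src <- integer(n_asv); seqs <- character(n_asv)
  seq_len_ref <- nchar(ref_db$seq[1])
  for (i in seq_len(n_asv)) {
    src[i] <- if (excluded[i] && length(exc_refs))
      sample(exc_refs, 1) else sample(het_refs, 1)
    seqs[i] <- switch(band[i],
      high = mutate_substitutions(ref_db$seq[src[i]], sample(0:2, 1)),
      mid  = mutate_substitutions(ref_db$seq[src[i]], sample(5:20, 1)),
      low  = random_seq(seq_len_ref))
  }
  ids <- sprintf("asv_%04d", seq_len(n_asv))
  base_abund <- rlnorm(n_asv, meanlog = 0, sdlog = design$sdlog)

  grid <- expand.grid(island = design$islands, depth_m = design$depth_strata,
                      stringsAsFactors = FALSE)
  grid$zone <- unname(design$depth_zones[as.character(grid$depth_m)])
  grid$sample <- sprintf("%s_%04dm", grid$island, grid$depth_m)
  grid$transect <- paste0("T", as.integer(factor(grid$island,
                                                 levels = design$islands)))
  grid$library_id <- paste0("L", rep_len(seq_len(design$n_libraries),
                                         nrow(grid)))
  grid$sample_role <- "environmental"

  counts <- matrix(0L, nrow(grid), n_asv,
                   dimnames = list(grid$sample, ids))
  member <- matrix(FALSE, nrow(grid), n_asv)
  for (s in seq_len(nrow(grid))) {
    in_pool <- pool_of == "core" |
      pool_of == paste0("zone:", grid$zone[s]) |
      pool_of == paste0("island:", grid$island[s])
    present <- in_pool & runif(n_asv) < design$occupancy
    member[s, ] <- present
    if (!any(present)) stopf("sample %s has an empty community", grid$sample[s])
    w <- base_abund[present]
    counts[s, present] <- as.integer(
      rmultinom(1, design$reads_per_sample, w / sum(w)))
  }

  keep <- colSums(counts) > 0
  truth <- list(
    asv = data.frame(asv = ids, pool = pool_of, source_ref = ref_db$id[src],
                     band = band,
                     functional_class = ifelse(band == "low", "unassigned",
                                               ref_class[src]),
                     base_abundance = base_abund, sampled = keep,
                     stringsAsFactors = FALSE),
    membership = member,
    samples = grid
  )
  meta <- grid[, c("sample", "island", "depth_m", "transect", "library_id",
                   "sample_role")]
  list(counts = counts[, keep, drop = FALSE],
       seqs = seq_records(ids[keep], seqs[keep]),
       metadata = meta, truth = truth, ref_db = ref_db)
}

#' Simulate a complete study: reference DB, mocks and environmental data
#'
#' Convenience wrapper producing everything the pipeline consumes: a
#' reference database, one mock library per sequencing library, the
#' environmental dataset, and combined metadata (each environmental
#' sample's library carries its mock, as the calibration requires).
#'
#' @param seed integer RNG seed.
#' @param design an [env_design()]; its seed is overridden by `seed`.
#' @param mock_args list of arguments passed on to [mock_design()].
#' @return list with `ref_db`, `env` (see [generate_env_dataset()]),
#'   `mocks` (named per library), and `metadata` covering environmental
#'   and mock samples.
#' @export
simulate_study <- function(seed = 1, design = env_design(),
                           mock_args = list()) {
  design$seed <- seed
  env <- generate_env_dataset(design)
  # the mock species are cultivated strains present in the reference DB;
  # the same nine-species mix is added to every library
  het <- env$ref_db[functional_class(env$ref_db$lineage) == "heterotroph", ]
  expected <- het[seq_len(min(9, nrow(het))), , drop = FALSE]
  libs <- sort(unique(env$metadata$library_id))
  # per-library seeds drawn from the study stream rather than taken as
  # consecutive integers: consecutive Mersenne-Twister seeds yield
  # correlated streams
  mock_seeds <- sample.int(.Machine$integer.max, length(libs))
  mocks <- lapply(seq_along(libs), function(i) {
    args <- c(list(expected = expected,
                   sample_id = paste0("mock_", libs[i]),
                   seed = mock_seeds[i]), mock_args)
    generate_mock_library(do.call(mock_design, args))
  })
  names(mocks) <- libs
  mock_meta <- data.frame(sample = paste0("mock_", libs),
                          island = NA_character_, depth_m = NA_integer_,
                          transect = NA_character_, library_id = libs,
                          sample_role = "mock", stringsAsFactors = FALSE)
  list(ref_db = env$ref_db, env = env, mocks = mocks, expected = expected,
       metadata = rbind(env$metadata, mock_meta))
}
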