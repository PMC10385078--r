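#' Default functional-exclusion configuration
#'
#' The study's focal fraction are heterotrophic protists: ASVs assigned to
#' metazoans, fungi, streptophytes or exclusively phototrophic taxa are
#' excluded. No canonical list of phototrophic divisions exists, so the
#' classification is a configurable map from PR2 divisions to functional
#' classes; the defaults cover the divisions the synthetic reference
#' database emits plus the common phototroph divisions.
#'
#' @return named list of character vectors of division names, one per
#'   excluded class (`metazoa`, `fungi`, `streptophyte`, `phototroph`).
#' @export
exclusion_config <- function() {
  list(
    metazoa      = "Metazoa",
    fungi        = "Fungi",
    streptophyte = "Streptophyta",
    phototroph   = c("Chlorophyta", "Rhodophyta", "Glaucophyta",
                     "Haptophyta", "Cryptophyta", "Prasinodermophyta")
  )
}

#' Classify lineages into functional groups
#'
#' @param lineages character vector of PR2-style lineage strings; `NA`
#'   means unassigned.
#' @param config an [exclusion_config()] list.
#' @return character vector over
#'   `heterotroph, metazoa, fungi, streptophyte, phototroph, unassigned`.
#' @export
functional_class <- function(lineages, config = exclusion_config()) {
  div <- lineage_division(lineages)
  out <- rep("heterotroph", length(div))
  out[is.na(div)] <- "unassigned"
  for (cls in names(config)) out[div %in% config[[cls]]] <- cls
  out
}

#' Read a YAML run configuration
#'
#' A single YAML file names the input paths and the analysis settings used
#' by a full run: count table, sequences, reference database, mock
#' references, metadata, identity cutoffs, depth groupings, permutation
#' counts and seeds. Missing settings fall back to package defaults.
#'
#' @param path path to a YAML file.
#' @return a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    min_identity = 80,
    low_identity_min = 98,
    max_mismatch = 1,
    n_perm = 999,
    seed = 1,
    depth_strata = c(50, 150, 300, 500, 1000, 1500, 2000),
    depth_zones = depth_zone_grouping(),
    depth_sharing = depth_sharing_grouping()
  )
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  cfg
}

#' Depth groupings used by the analyses
#'
#' Two named groupings of the seven sampling depths are used: the three
#' bathymetric zones that structure the ordination and PermANOVA
#' (sublittoral 50 m, upper bathyal 150-500 m, lower bathyal 1000-2000 m),
#' and the five-way grouping used for shared/unique ASV accounting
#' (50, 150, 300-500, 1000-1500, 2000 m).
#'
#' @return named character vector mapping depth (as character, metres) to
#'   group label.
#' @export
depth_zone_grouping <- function() {
  c(`50` = "sublittoral",
    `150` = "upper_bathyal", `300` = "upper_bathyal", `500` = "upper_bathyal",
    `1000` = "lower_bathyal", `1500` = "lower_bathyal",
    `2000` = "lower_bathyal")
}

#' @rdname depth_zone_grouping
#' @export
depth_sharing_grouping <- function() {
  c(`50` = "50", `150` = "150",
    `300` = "300-500", `500` = "300-500",
    `1000` = "1000-1500", `1500` = "1000-1500",
    `2000` = "2000")
}
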