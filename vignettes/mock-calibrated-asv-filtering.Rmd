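---
title: "Mock-calibrated ASV filtering and community structure: methods"
author: "mockasv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mock-calibrated ASV filtering and community structure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockasv)
```

## The analysis this package implements

Benthic metabarcoding surveys of heterotrophic protists sequence the ~130 nt
V9 region of the 18S rRNA gene from sediment DNA, denoise reads into
amplicon sequence variants (ASVs), and ask how community composition is
structured by depth and by site (here: seven bathymetric strata, 50–2000 m,
around three oceanic islands, 21 samples). Two methodological problems
dominate such datasets and are the focus of this package:

1. **Noise filtering.** Denoised tables still contain low-abundance
   artefacts (residual PCR/sequencing error, index cross-talk). A mock
   community — a mix of nine known protist species co-sequenced on every
   library — provides an internal yardstick: any ASV in the mock that is
   not one of the nine species is noise at a known read proportion, and
   that proportion can be turned into a per-library filtering threshold.
2. **Inference on presence/absence structure.** With heavy-tailed rRNA
   copy-number variation, presence/absence (Jaccard) beta diversity with
   permutation-based inference (PermANOVA, NMDS) is the appropriate
   toolset; it is implemented here with explicit, testable definitions.

The package starts from denoised output (ASV count table + sequences); raw
read processing (trimming, denoising, merging, chimera removal) is out of
scope.

## Threshold calibration from mock communities

Let a mock sample have total reads $N$ and ASVs with reads $n_a$. Each ASV
is matched by global unit-cost edit distance to the expected species; a
distance of at most one mismatch still counts as "assigned" to a species
(sequencing-error variants of a true species remain attributable to it).

* **Lenient threshold** $t_\ell = \min_{a \in \text{matched}} n_a / N$ —
  the read proportion of the matched ASV with the fewest reads. Applied
  per environmental sample with *keep-if-$\ge$* semantics, so the defining
  ASV itself would survive at its own threshold; this matches the rule
  that ASVs with *less than* the threshold proportion are removed.
* **Strict threshold** $t_s = \max_{a \notin \text{expected}} n_a / N$,
  where the *expected* set is the distance-0 ASV of each species. One-
  mismatch variants count as matched for the lenient rule but are noise
  for the strict rule — the only reading under which strict thresholds
  (≈0.8% in this study system) exceed lenient ones (≈0.09%). $t_s$ is an
  exclusive bound applied with *keep-if-$>$* semantics, which avoids
  inventing an arbitrary offset above the largest noise ASV. The bound is
  *feasible* when every expected ASV's proportion strictly exceeds it;
  filtering the mock at its own feasible $t_s$ returns exactly the nine
  expected ASVs, which the test suite asserts.
* **Low-abundance dataset.** Cells removed by the lenient filter are kept
  in a third table, restricted to ASVs whose best reference identity is
  strictly above 98% — rarely occurring genotypes are retained while
  "noisy" unassignable ASVs are not. Per sample, the main and
  low-abundance tables are disjoint by construction.

Decisions where the source material is silent, made once and fixed:

* Proportion denominators are the per-sample totals of the table *at the
  point of filtering* (after restriction to heterotroph ASVs). The
  alternative (totals before functional filtering) changes thresholds by
  a near-constant factor; the per-sample wording of the rule is preserved
  either way.
* Mock matching uses full edit distance (indels allowed), not Hamming
  distance: denoisers emit length variants, and for distance ≤ 1 the two
  notions differ only for single-indel variants, which are real error
  modes.
* Thresholds are applied per sample and per library, never globally.

## Taxonomic assignment

Assignment is by best-hit global pairwise alignment against a PR2-style
reference database (8-rank lineages; rank 3, the division, drives the
composition profiles). The aligner scores match 0, mismatch 1, gap 1,
end-to-end; identity is

$$\mathrm{id}(a,b) = 100\,\frac{L - e}{L},$$

with $e$ the edit distance and $L$ the column count of the edit-optimal
alignment with the fewest gap columns (making $L$, hence identity,
deterministic). The original analysis used vsearch's `usearch_global`,
whose exact gap penalties and identity definition (`iddef`) are not
documented in the study; the unit-cost definition above is stated
explicitly instead, and both cutoffs are configurable. Cutoffs are strict
inequalities — identity must exceed 80% for assignment and 98% for the
low-abundance dataset — mirroring the ">80%" / ">98%" wording. Ties
between references break to the lexicographically smallest reference id,
so results are independent of reference order. ASVs assigned to
metazoans, fungi, streptophytes or exclusively phototrophic divisions are
excluded; because no canonical list of "exclusively phototrophic taxa"
exists, the division-to-class map is a configuration object
(`exclusion_config()`). Genotype rediscovery (`find_genotype()`) sums
reads over ASVs at exactly 100% identity to a cultivated strain's
sequence.

## Diversity and community structure

* **Shannon index**: $H = -\sum p_i \ln p_i$ (natural log, the vegan
  default; base configurable).
* **Rarefaction** is analytic (hypergeometric):
  $E[S_n] = \sum_i \left[1 - \binom{N-N_i}{n}\big/\binom{N}{n}\right]$ —
  deterministic, and validated in tests against a 10^4-draw resampling
  oracle to within three standard errors.
* **Jaccard distance** on presence/absence,
  $d_{ij} = 1 - |A_i \cap A_j|/|A_i \cup A_j|$.
* **NMDS** minimises Kruskal stress-1,
  $\sqrt{\sum (d^{conf}_{ij} - \hat d_{ij})^2 / \sum (d^{conf}_{ij})^2}$,
  with $\hat d$ the isotonic regression of configuration distances on the
  rank order of the observed dissimilarities, iterated by SMACOF
  majorisation (Guttman transform). Defaults: 20 starts (one metric-
  scaling start plus random starts), tolerance $10^{-7}$ on the stress
  change, 500 iterations; the best start is reported with its stress and
  convergence flag. This engine is not a bit-for-bit reproduction of
  vegan's `metaMDS`; tests check the properties that matter — recovery of
  Euclidean-recoverable configurations at near-zero stress, and
  invariance of the solution under monotone transformation of the input
  distances.
* **PermANOVA**: $SS_{total} = \sum_{i<j} d_{ij}^2 / n$, within-group
  sums with each group's own size, pseudo-
  $F = (SS_b/(g-1))/(SS_w/(n-g))$, and
  $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$ under free
  permutation of sample labels, so $p \ge 1/(n_{perm}+1)$. For tiny
  designs an exact mode enumerates all $n!$ permutations. Pairwise tests
  report Benjamini–Hochberg adjusted p-values alongside raw ones.
* **Nested PermANOVA** (islands, depths nested within islands) uses the
  Gower-centred inner-product matrix and sequential (Type-I) projections,
  island first — mirroring the stated model order — with each term tested
  against the residual under free permutation. Free permutation matches
  `adonis2`'s default; the correct exchangeability unit for a nested
  design is debatable, so this is a documented default rather than a
  claim. With one sample per island-by-stratum cell the stratum-level
  nested term saturates the design (zero residual df); the nested test is
  therefore run on the three bathymetric *zones* (50 m; 150–500 m;
  1000–2000 m) within islands, and the function refuses saturated
  designs rather than dividing by zero.
* **Set partitioning** uses exact intersection (UpSet) semantics: each
  ASV falls in exactly one group-combination cell, so cell counts sum to
  the ASV total (asserted on every run). Two named depth groupings are
  used: the three zones above for ordination/PermANOVA, and a five-way
  grouping (50; 150; 300–500; 1000–1500; 2000 m) for shared/unique
  accounting. Reported percentages use the analysed dataset's total ASV
  count as denominator and are rounded half-up; raw values are retained.

## The synthetic-data generator

Because the study's read data cannot be reprocessed at desk scale, every
stage is validated against generated data with recorded ground truth.

**Mock libraries** (`mock_design()`, `generate_mock_library()`). Counts
are drawn by a single multinomial at fixed depth — proportions, the unit
the thresholds act on, are then exactly the designed values in
expectation. The default design is nine expected species at equal shares
of 98.5% of reads, one 1-mismatch error variant at 0.5% and one unrelated
contaminant (edit distance ≥ 2 from every species) at 1.0%: a designed
lenient threshold of 0.5% and strict bound of 1.0%, roughly an order of
magnitude above the study's real thresholds so that recovery can be
scored at 10^5 reads without millions of reads per mock. Designed
proportions summing to less than one are renormalised and the
renormalised values recorded as truth. The composition of the real
nine-species mix beyond its species count is not published; the symmetric
default is a neutral stand-in.

**Environmental datasets** (`env_design()`, `generate_env_dataset()`).
Twenty-one samples (3 islands × 7 strata) assemble from three disjoint
ASV pools: a core pool present everywhere (40 ASVs), zone-specific pools
(25 per bathymetric zone) and island-specific pools (20 per island) —
the planted, detectable analogue of the depth-zone and island effects the
study reports. Per-ASV abundances are log-normal (σ = 1; no abundance
model is published, and log-normal is the standard choice for community
abundance data), presence is thinned by an occupancy probability of 0.9,
and counts are multinomial at 10^5 reads per sample. ASV sequences derive
from a generated PR2-style reference database (pairwise identity < 95%)
either exactly, mutated into the >98% or 80–98% identity bands, or
replaced by unrelated sequences below 80%, so both identity cutoffs are
exercised; a 15% fraction sources from excluded divisions to exercise
functional filtering. Setting the zone and island pools to zero yields
exchangeable samples — the null model used to calibrate the permutation
tests.

What the generator deliberately does **not** emulate: read-level error
profiles, chimeras (contaminants stand in abstractly), rRNA copy-number
variation, tag-jumping, spatial autocorrelation within transects, and
uneven sequencing depth. Passing tests therefore demonstrate correctness
of the calibration and inference machinery under the stated model, not
robustness to every artefact of real libraries.

**Seeds.** All generators take integer seeds and are deterministic under
them. Replicate seeds inside `simulate_study()` and the validation
scripts are drawn from a master RNG stream rather than taken as
consecutive integers: consecutive Mersenne-Twister seeds yield correlated
streams, which measurably distorted simulated error rates during
development.

## Validation problem sizes

The shipped validation uses: 100 mock libraries at 10^5 reads for
threshold recovery (tolerance ±2 standard errors of a multinomial
proportion); 1000 null datasets (21 samples, three groups of seven,
199 permutations) for type-I calibration of PermANOVA at the 5% level;
100 datasets with the planted three-zone structure for power at the 1%
level; 1000 random short sequence pairs against an exhaustive alignment
oracle; and exact permutation enumeration on four-sample designs. These
sizes give stable rates while keeping the default validation run in the
order of a minute per property.

## Known limitations

* The alignment identity definition approximates, but is not identical
  to, vsearch's; absolute identities near a cutoff can differ between
  the two for gappy alignments.
* The strict threshold is undefined (errors) when a mock lacks a
  distance-0 ASV for some species; partial-mock recovery is not
  attempted.
* Nested PermANOVA offers only free permutation; restricted permutation
  schemes (e.g. permuting within islands) are not implemented.
* NMDS uses primary tie handling in the isotonic step; datasets dominated
  by tied dissimilarities may converge to different but equally valid
  configurations across platforms if BLAS rounding differs.
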