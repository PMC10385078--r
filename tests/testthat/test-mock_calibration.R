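make_match <- function(reads, species, dist, total = sum(reads)) {
  out <- data.frame(asv = sprintf("a%02d", seq_along(reads)),
                    matched_species = species, edit_distance = dist,
                    reads = reads, proportion = reads / total,
                    stringsAsFactors = FALSE)
  attr(out, "total_reads") <- total
  attr(out, "n_expected") <- length(unique(species[!is.na(species) & dist == 0]))
  class(out) <- c("mock_match", "data.frame")
  out
}

test_that("mock matching assigns ASVs by minimum edit distance", {
  expected <- seq_records(c("sp1", "sp2", "sp3"),
                          c("AAAAAAAAAACCCCCCCCCC",
                            "GGGGGGGGGGTTTTTTTTTT",
                            "ACACACACACGTGTGTGTGT"))
  asv_seqs <- seq_records(
    c("m1", "m2", "m3"),
    c("ACACACACACGTGTGTGTGT",    # identical to sp3
      "ACACACACACGTGTGTGTGA",    # one substitution from sp3
      "AAAAAGGGGGCCCCCTTTTT"))   # far from everything
  counts <- matrix(c(500L, 300L, 200L), 1,
                   dimnames = list("mock", c("m1", "m2", "m3")))
  mm <- match_mock(counts, asv_seqs, expected)
  expect_equal(mm$matched_species, c("sp3", "sp3", NA))
  expect_equal(mm$edit_distance[1:2], c(0L, 1L))
  expect_equal(sum(mm$proportion), 1)
  expect_error(match_mock(rbind(counts, counts), asv_seqs, expected),
               "exactly one sample")
})

test_that("lenient threshold is the smallest matched ASV's proportion", {
  mm <- make_match(reads = c(900, 90, 10),
                   species = c("sp1", "sp2", NA), dist = c(0, 0, 5))
  expect_equal(lenient_threshold(mm), 0.09)
  none <- make_match(reads = 100, species = NA_character_, dist = 4)
  expect_error(lenient_threshold(none), "mock failed")
  single <- make_match(reads = 1000, species = "sp1", dist = 0)
  expect_equal(lenient_threshold(single), 1.0)
})

test_that("strict threshold bounds the largest non-expected ASV", {
  mm <- make_match(reads = c(400, 300, 200, 10),
                   species = c("sp1", "sp2", "sp3", "sp1"),
                   dist = c(0, 0, 0, 1))
  st <- strict_threshold(mm)
  expect_equal(st$t_strict, 10 / 910)
  expect_true(st$feasible)

  clean <- make_match(reads = c(600, 400), species = c("sp1", "sp2"),
                      dist = c(0, 0))
  st0 <- strict_threshold(clean)
  expect_equal(st0$t_strict, 0)
  expect_true(st0$feasible)

  # a dominant contaminant exceeding an expected species: infeasible
  bad <- make_match(reads = c(500, 50, 450),
                    species = c("sp1", "sp2", NA), dist = c(0, 0, 7))
  stb <- strict_threshold(bad)
  expect_equal(stb$t_strict, 0.45)
  expect_false(stb$feasible)

  incomplete <- make_match(reads = c(900, 100),
                           species = c("sp1", "sp1"), dist = c(0, 1))
  attr(incomplete, "n_expected") <- 9
  expect_error(strict_threshold(incomplete), "mock incomplete")
})

two_library_fixture <- function() {
  counts <- matrix(c(9L, 8L, 9983L,
                     50L, 5L, 9945L), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  meta <- data.frame(sample = c("s1", "s2"), library_id = c("L1", "L2"),
                     stringsAsFactors = FALSE)
  th <- data.frame(library_id = c("L1", "L2"),
                   t_lenient = c(0.0009, 0.003),
                   t_strict = c(0.002, 0.004),
                   feasible_strict = TRUE, stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, th = th)
}

test_that("threshold application is per-sample with keep-if->= semantics", {
  fx <- two_library_fixture()
  main <- apply_threshold(fx$counts, fx$meta, fx$th, "lenient")
  # s1 total 10000, t 0.0009: 9 reads (0.09%) kept, 8 reads removed
  expect_equal(main["s1", "a1"], 9L)
  expect_false("a2" %in% colnames(main) && main["s1", "a2"] > 0)
  # s2 total 10000, t 0.003: 50 reads kept, 5 removed
  expect_equal(main["s2", "a1"], 50L)
  log <- attr(main, "removal_log")
  expect_equal(log$s1$reads_removed, 8L)
  expect_equal(log$s2$reads_removed, 5L)

  zero <- fx$th; zero$t_lenient <- 0
  expect_equal(apply_threshold(fx$counts, fx$meta, zero, "lenient"),
               fx$counts, ignore_attr = TRUE)
})

test_that("strict mode drops proportions equal to the bound", {
  counts <- matrix(c(20L, 80L, 9900L), 1,
                   dimnames = list("s1", c("a1", "a2", "a3")))
  meta <- data.frame(sample = "s1", library_id = "L1")
  th <- data.frame(library_id = "L1", t_lenient = 0, t_strict = 0.002,
                   feasible_strict = TRUE)
  strict <- apply_threshold(counts, meta, th, "strict")
  expect_false("a1" %in% colnames(strict))  # 0.002, not strictly greater
  expect_equal(strict[1, "a2"], 80L)
})

test_that("thresholding is scale invariant and monotone in the threshold", {
  fx <- two_library_fixture()
  scaled <- fx$counts * 7L
  a <- apply_threshold(fx$counts, fx$meta, fx$th, "lenient")
  b <- apply_threshold(scaled, fx$meta, fx$th, "lenient")
  expect_identical(colnames(a), colnames(b))
  expect_identical(unname(a > 0), unname(b > 0))

  set.seed(8)
  counts <- matrix(rpois(60, 40), 4, 15,
                   dimnames = list(paste0("s", 1:4), paste0("a", 1:15)))
  storage.mode(counts) <- "integer"
  meta <- data.frame(sample = paste0("s", 1:4), library_id = "L1")
  keep_sets <- lapply(c(0.005, 0.02, 0.05), function(t) {
    th <- data.frame(library_id = "L1", t_lenient = t, t_strict = t,
                     feasible_strict = TRUE)
    colnames(apply_threshold(counts, meta, th, "lenient"))
  })
  expect_true(all(keep_sets[[2]] %in% keep_sets[[1]]))
  expect_true(all(keep_sets[[3]] %in% keep_sets[[2]]))
})

test_that("partitioning separates main, strict and low-abundance reads", {
  # a2 is below threshold in s1 but above it in s2
  counts <- matrix(c(9960L, 30L, 10L,
                     9000L, 940L, 60L), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  meta <- data.frame(sample = c("s1", "s2"), library_id = "L1")
  th <- data.frame(library_id = "L1", t_lenient = 0.005, t_strict = 0.008,
                   feasible_strict = TRUE)
  assign <- data.frame(asv = c("a1", "a2", "a3"),
                       identity_pct = c(100, 99.2, 90),
                       best_ref = "r1", stringsAsFactors = FALSE)
  part <- partition_datasets(counts, meta, th, assign)
  expect_equal(part$main["s1", "a2"], 0L)
  expect_equal(part$main["s2", "a2"], 940L)
  # removed cell of a2 (identity > 98) lands in the low-abundance set
  expect_equal(part$low_abundant["s1", "a2"], 30L)
  expect_equal(part$low_abundant["s2", "a2"], 0L)
  # a3 removed everywhere but identity 90: excluded from low-abundance
  expect_false("a3" %in% colnames(part$low_abundant))
  # per-sample disjointness of main and low-abundance cells
  common <- intersect(colnames(part$main), colnames(part$low_abundant))
  expect_true(all(part$main[, common] * part$low_abundant[, common] == 0))

  allkept <- partition_datasets(counts, meta,
                                transform(th, t_lenient = 0), assign)
  expect_equal(ncol(allkept$low_abundant), 0)
})

test_that("calibration recovers designed thresholds on a generated mock", {
  ml <- generate_mock_library(mock_design(seed = 77))
  th <- calibrate_thresholds(list(L1 = ml))
  se_l <- sqrt(0.005 * 0.995 / 1e5)
  se_s <- sqrt(0.01 * 0.99 / 1e5)
  expect_lt(abs(th$t_lenient - 0.005), 2 * se_l)
  expect_lt(abs(th$t_strict - 0.01), 2 * se_s)
  expect_true(th$feasible_strict)
})
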