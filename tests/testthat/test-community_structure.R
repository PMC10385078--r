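test_that("Jaccard distances follow the set formula", {
  m <- matrix(c(1, 1, 1, 0,
                0, 1, 1, 1,
                1, 1, 1, 0,
                0, 0, 0, 1), 4, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("a", 1:4)))
  d <- as.matrix(jaccard_matrix(m))
  expect_equal(d["s1", "s2"], 0.5)   # |A & B| = 2, |A | B| = 4
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s4"], 1)
  expect_error(jaccard_matrix(rbind(m, s5 = c(0, 0, 0, 0))),
               "no ASVs present")
})

test_that("NMDS recovers a planar configuration with near-zero stress", {
  set.seed(2)
  pts <- matrix(rnorm(12), 6, 2)
  d <- dist(pts)
  fit <- nmds(d, n_starts = 10, seed = 4)
  expect_lt(fit$stress, 0.01)
  fit2 <- nmds(d, n_starts = 10, seed = 4)
  expect_identical(fit$points, fit2$points)
})

test_that("NMDS is insensitive to monotone transformation of distances", {
  set.seed(6)
  pts <- matrix(rnorm(16), 8, 2)
  d <- dist(pts)
  f1 <- nmds(d, n_starts = 10, seed = 9)
  f2 <- nmds(d^1.5, n_starts = 10, seed = 9)
  expect_lt(abs(f1$stress - f2$stress), 0.05)
  r <- cor(as.vector(dist(f1$points)), as.vector(dist(f2$points)),
           method = "spearman")
  expect_gt(r, 0.95)
})

perm_fixture <- function(seed = 19, n = 12, g = 3) {
  set.seed(seed)
  pres <- matrix(rbinom(n * 30, 1, 0.4), n, 30,
                 dimnames = list(paste0("s", seq_len(n)), NULL))
  pres[cbind(seq_len(n), seq_len(n))] <- 1
  labels <- rep(LETTERS[seq_len(g)], length.out = n)
  list(d = jaccard_matrix(pres), labels = labels)
}

test_that("PermANOVA pseudo-F and R2 agree with vegan::adonis2", {
  fx <- perm_fixture()
  fit <- permanova(fx$d, fx$labels, n_perm = 99, seed = 1)
  df <- data.frame(labels = fx$labels)
  ref <- vegan::adonis2(fx$d ~ labels, data = df, permutations = 2)
  expect_equal(fit$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(fit$tab$SumOfSqs, ref$SumOfSqs[c(1, 2, 3)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PermANOVA is invariant to relabeling and sample order", {
  fx <- perm_fixture()
  f1 <- permanova(fx$d, fx$labels, n_perm = 49, seed = 2)
  relab <- c(A = "x", B = "y", C = "z")[fx$labels]
  f2 <- permanova(fx$d, relab, n_perm = 49, seed = 2)
  expect_equal(f1$pseudo_F, f2$pseudo_F)
  expect_equal(f1$p_value, f2$p_value)
  ord <- sample(length(fx$labels))
  f3 <- permanova(as.matrix(fx$d)[ord, ord], fx$labels[ord],
                  n_perm = 49, seed = 2)
  expect_equal(f1$pseudo_F, f3$pseudo_F)
})

test_that("permutation p-values respect their lower bound and seed", {
  fx <- perm_fixture()
  fit <- permanova(fx$d, fx$labels, n_perm = 19, seed = 3)
  expect_gte(fit$p_value, 1 / 20)
  expect_equal(fit$p_value,
               permanova(fx$d, fx$labels, n_perm = 19, seed = 3)$p_value)
})

test_that("exact enumeration matches a brute-force permutation oracle", {
  set.seed(23)
  pres <- matrix(rbinom(4 * 12, 1, 0.5), 4, 12,
                 dimnames = list(paste0("s", 1:4), NULL))
  pres[, 1] <- 1
  d <- jaccard_matrix(pres)
  labels <- c("A", "A", "B", "B")
  fit <- permanova(d, labels, permutations = "exact")
  # oracle: adonis2's F on every relabelling of the 4 samples
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  F_all <- apply(perms, 1, function(p) {
    df <- data.frame(lab = labels[p])
    vegan::adonis2(d ~ lab, data = df, permutations = 2)$F[1]
  })
  F_obs <- vegan::adonis2(d ~ lab, data = data.frame(lab = labels),
                          permutations = 2)$F[1]
  expect_equal(fit$p_value, mean(F_all >= F_obs - 1e-12))
  expect_equal(fit$n_perm, 24)
})

test_that("no-effect constructions give F near 1 and large p", {
  # distances all equal: every partition explains nothing
  n <- 9
  d <- matrix(0.5, n, n); diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  fit <- permanova(d, rep(c("A", "B", "C"), each = 3), n_perm = 99, seed = 1)
  expect_equal(fit$pseudo_F, 1, tolerance = 1e-10)
  expect_equal(fit$p_value, 1)
})

test_that("pairwise PermANOVA covers all pairs and adjusts p-values", {
  fx <- perm_fixture(n = 12, g = 3)
  pw <- pairwise_permanova(fx$d, fx$labels, n_perm = 49, seed = 5)
  expect_equal(nrow(pw), 3)
  expect_setequal(paste(pw$group1, pw$group2),
                  c("A B", "A C", "B C"))
  expect_equal(pw$p_adjusted, p.adjust(pw$p_value, "BH"))
  # flat distances: raw p all 1 stays 1 after adjustment
  n <- 9
  d <- matrix(0.5, n, n); diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  pw1 <- pairwise_permanova(d, rep(c("A", "B", "C"), each = 3),
                            n_perm = 19, seed = 1)
  expect_true(all(pw1$p_value == 1))
  expect_true(all(pw1$p_adjusted == 1))
})

test_that("nested PermANOVA decomposes sequentially and matches adonis2", {
  sim <- make_fixture_study(seed = 29)
  d <- jaccard_matrix(sim$env$counts)
  meta <- sim$env$metadata
  zone <- depth_zone_grouping()[as.character(meta$depth_m)]
  fit <- nested_permanova(d, meta$island, zone, n_perm = 49, seed = 7)
  expect_equal(sum(fit$tab$R2[1:3]), 1, tolerance = 1e-10)
  df <- data.frame(island = factor(meta$island), zone = factor(zone))
  ref <- vegan::adonis2(d ~ island + island:zone, data = df,
                        permutations = 2, by = "terms")
  expect_equal(fit$tab$SumOfSqs[1], ref$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(fit$tab$SumOfSqs[2], ref$SumOfSqs[2], tolerance = 1e-8)
  expect_equal(fit$tab$F[1], ref$F[1], tolerance = 1e-8)
  expect_equal(fit$tab$F[2], ref$F[2], tolerance = 1e-8)
})

test_that("nested PermANOVA refuses saturated designs", {
  sim <- make_fixture_study(seed = 31)
  d <- jaccard_matrix(sim$env$counts)
  meta <- sim$env$metadata
  expect_error(nested_permanova(d, meta$island, meta$depth_m,
                                n_perm = 9, seed = 1),
               "residual degrees of freedom")
})

test_that("a planted island effect loads on the island term", {
  design <- env_design(core_size = 20, zone_size = 0, island_size = 15,
                       reads_per_sample = 2e4, seed = 37)
  env <- generate_env_dataset(design)
  d <- jaccard_matrix(env$counts)
  zone <- depth_zone_grouping()[as.character(env$metadata$depth_m)]
  fit <- nested_permanova(d, env$metadata$island, zone,
                          n_perm = 199, seed = 2)
  expect_lt(fit$tab$p[1], 0.01)
  expect_gt(fit$tab$p[2], 0.1)
})
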