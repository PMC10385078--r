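#' Jaccard distance matrix on presence/absence
#'
#' `d(i, j) = 1 - |A_i & A_j| / |A_i | A_j|` over the ASV sets of two
#' samples; computed via [vegan::vegdist()] with binary transformation.
#'
#' @param counts counts (or presence) matrix, samples x ASVs.
#' @return a `dist` object over samples.
#' @export
jaccard_matrix <- function(counts) {
  pres <- counts > 0
  if (any(rowSums(pres) == 0))
    stopf("sample %s has no ASVs present",
          rownames(counts)[rowSums(pres) == 0][1])
  vegan::vegdist(pres, method = "jaccard", binary = TRUE)
}

# SMACOF majorisation with primary monotone regression on the
# dissimilarity order; returns the configuration and Kruskal stress-1
nmds_engine <- function(dmat, ord, x, max_iter, tol) {
  n <- nrow(x)
  low <- lower.tri(dmat)
  stress_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- as.matrix(dist(x))
    evec <- e[low]
    dhat_v <- numeric(length(evec))
    dhat_v[ord] <- isoreg(evec[ord])$yf
    stress <- sqrt(sum((evec - dhat_v)^2) / sum(evec^2))
    if (abs(stress_prev - stress) < tol) { converged <- TRUE; break }
    stress_prev <- stress
    dhat <- matrix(0, n, n)
    dhat[low] <- dhat_v
    dhat <- dhat + t(dhat)
    # Guttman transform
    b <- ifelse(e > 0, -dhat / e, 0)
    diag(b) <- -rowSums(b)
    x <- b %*% x / n
  }
  list(points = x, stress = stress, converged = converged)
}

#' Non-metric multidimensional scaling
#'
#' Rank-based ordination minimising Kruskal stress-1,
#' `sqrt(sum((d_conf - dhat)^2) / sum(d_conf^2))`, where `dhat` is the
#' monotone (isotonic) regression of the configuration distances on the
#' order of the observed dissimilarities. Iterative majorisation (SMACOF
#' Guttman transform) from a metric-scaling start plus `n_starts - 1`
#' random starts; the lowest-stress solution is returned, centred and
#' rotated to its principal axes. Deterministic under a fixed seed.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param k target dimensionality (default 2).
#' @param n_starts number of initial configurations.
#' @param max_iter,tol majorisation iteration controls.
#' @param seed integer RNG seed for the random starts.
#' @return list of class `nmds_fit` with `points` (samples x k), `stress`,
#'   `n_starts`, `best_start`, `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 500, tol = 1e-7,
                 seed = 1) {
  dmat <- as.matrix(d)
  n <- nrow(dmat)
  if (n <= k) stopf("need more samples than dimensions")
  if (all(dmat == 0)) stopf("all dissimilarities are zero")
  set.seed(seed)
  low <- lower.tri(dmat)
  dvec <- dmat[low]
  ord <- order(dvec)
  init <- vector("list", n_starts)
  init[[1]] <- tryCatch(cmdscale(dmat, k = k), error = function(e) NULL)
  if (is.null(init[[1]]) || ncol(init[[1]]) < k)
    init[[1]] <- matrix(rnorm(n * k), n, k)
  for (i in seq_len(n_starts)[-1]) init[[i]] <- matrix(rnorm(n * k), n, k)
  best <- NULL; best_start <- NA_integer_
  for (i in seq_len(n_starts)) {
    fit <- nmds_engine(dmat, ord, init[[i]], max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit; best_start <- i
    }
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  pts <- pts %*% prcomp(pts)$rotation
  dimnames(pts) <- list(rownames(dmat), paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress, n_starts = n_starts,
                 best_start = best_start, converged = best$converged),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples, %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  cat(sprintf("Kruskal stress-1: %.4f (best of %d starts%s)\n", x$stress,
              x$n_starts, if (x$converged) "" else ", not converged"))
  invisible(x)
}

# squared-distance sums of squares for a one-factor design
permanova_stats <- function(d2, grp, SS_total, n) {
  SSw <- 0
  for (g in unique(grp)) {
    i <- grp == g
    SSw <- SSw + sum(d2[i, i]) / (2 * sum(i))
  }
  SSb <- SS_total - SSw
  g <- length(unique(grp))
  F <- (SSb / (g - 1)) / (SSw / (n - g))
  c(F = F, R2 = SSb / SS_total, SSb = SSb, SSw = SSw)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' One-factor PermANOVA on a distance matrix
#'
#' Distance-based multivariate analysis of variance (Anderson's method):
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` summed per group with its
#' own size, pseudo-F `(SS_between/(g-1)) / (SS_within/(n-g))`. The
#' p-value permutes sample labels freely; with `n_perm` random permutations
#' it is `(1 + #[F_perm >= F_obs]) / (1 + n_perm)`, so it can never fall
#' below `1/(n_perm + 1)`. With `permutations = "exact"` all `n!`
#' permutations are enumerated (small n only) and the p-value is the exact
#' fraction with `F_perm >= F_obs` (the identity permutation included).
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param labels group labels, one per sample.
#' @param n_perm number of random permutations.
#' @param seed integer RNG seed for the permutations.
#' @param permutations `"random"` (default) or `"exact"`.
#' @return list of class `permanova_fit` with `pseudo_F`, `R2`, `p_value`,
#'   `df`, `n_perm`, `seed` and a `tab` data frame.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1,
                      permutations = c("random", "exact")) {
  permutations <- match.arg(permutations)
  dmat <- as.matrix(d)
  n <- nrow(dmat)
  labels <- as.character(labels)
  if (length(labels) != n) stopf("one label per sample required")
  g <- length(unique(labels))
  if (g < 2) stopf("need at least two groups")
  if (any(table(labels) < 1)) stopf("every group needs at least one sample")
  d2 <- dmat^2
  SS_total <- sum(d2) / (2 * n)
  obs <- permanova_stats(d2, labels, SS_total, n)
  if (permutations == "exact") {
    if (n > 8) stopf("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    Fp <- apply(perms, 1, function(p)
      permanova_stats(d2, labels[p], SS_total, n)[["F"]])
    p_value <- mean(Fp >= obs[["F"]])
    n_perm <- nrow(perms)
  } else {
    if (n_perm < 1) stopf("n_perm must be >= 1")
    set.seed(seed)
    count <- 0L
    for (b in seq_len(n_perm)) {
      Fp <- permanova_stats(d2, labels[sample.int(n)], SS_total, n)[["F"]]
      if (Fp >= obs[["F"]]) count <- count + 1L
    }
    p_value <- (1 + count) / (1 + n_perm)
  }
  tab <- data.frame(
    term = c("groups", "residual", "total"),
    Df = c(g - 1, n - g, n - 1),
    SumOfSqs = c(obs[["SSb"]], obs[["SSw"]], SS_total),
    R2 = c(obs[["R2"]], 1 - obs[["R2"]], 1),
    F = c(obs[["F"]], NA, NA),
    p = c(p_value, NA, NA))
  structure(list(pseudo_F = obs[["F"]], R2 = obs[["R2"]], p_value = p_value,
                 df = c(groups = g - 1, residual = n - g),
                 n_perm = n_perm, seed = seed, tab = tab),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat("PermANOVA (free permutation of sample labels)\n")
  print(x$tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pairwise PermANOVA between all group pairs
#'
#' Runs [permanova()] on the sub-matrix of every pair of groups and
#' reports Benjamini-Hochberg adjusted p-values alongside the raw ones.
#'
#' @inheritParams permanova
#' @return data frame with one row per pair: `group1`, `group2`,
#'   `pseudo_F`, `R2`, `p_value`, `p_adjusted`, `n_perm`.
#' @export
pairwise_permanova <- function(d, labels, n_perm = 999, seed = 1) {
  dmat <- as.matrix(d)
  labels <- as.character(labels)
  levs <- sort(unique(labels))
  if (length(levs) < 2) stopf("need at least two groups")
  pairs <- combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- labels %in% pairs[, k]
    if (sum(sel) < 2) {
      warnf("pair %s/%s has fewer than two samples; skipped",
            pairs[1, k], pairs[2, k])
      return(NULL)
    }
    fit <- permanova(dmat[sel, sel], labels[sel], n_perm, seed + k)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               pseudo_F = fit$pseudo_F, R2 = fit$R2, p_value = fit$p_value,
               n_perm = fit$n_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

# trace of H %*% G for symmetric G and a projection onto model matrix X
proj_trace <- function(X, G) {
  q <- qr(X)
  H <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
  list(ss = sum(H * G), rank = q$rank, H = H)
}

#' Two-factor nested PermANOVA (islands, depths nested within islands)
#'
#' Sequential (Type-I) decomposition on the Gower-centred inner-product
#' matrix: the island term enters first, then depth nested within island
#' (depth levels treated as distinct per island). Each term's pseudo-F is
#' tested against the residual; p-values come from free permutation of
#' samples. Note that with one sample per island-by-depth cell the nested
#' term at full depth resolution leaves no residual degrees of freedom —
#' use depth zones (see [depth_zone_grouping()]) as the nested factor.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param island,depth factors (or coercible), one value per sample.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @return list of class `nested_permanova_fit` with a `tab` of per-term
#'   `Df`, `SumOfSqs`, `R2`, `F`, `p`.
#' @export
nested_permanova <- function(d, island, depth, n_perm = 999, seed = 1) {
  dmat <- as.matrix(d)
  n <- nrow(dmat)
  island <- factor(island)
  depth <- factor(depth)
  cell <- interaction(island, depth, drop = TRUE)
  if (nlevels(cell) < nlevels(island) * nlevels(depth))
    warnf("nested term reduced: some depth levels span no samples within an island")
  A <- -0.5 * dmat^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  SS_total <- sum(diag(G))
  X1 <- stats::model.matrix(~island)
  X2 <- stats::model.matrix(~cell)
  stat <- function(Gp) {
    ss1 <- proj_trace(X1, Gp)
    ss12 <- proj_trace(X2, Gp)
    c(ss_island = ss1$ss, ss_depth = ss12$ss - ss1$ss,
      ss_res = SS_total - ss12$ss, rank1 = ss1$rank, rank2 = ss12$rank)
  }
  obs <- stat(G)
  df1 <- obs[["rank1"]] - 1
  df2 <- obs[["rank2"]] - obs[["rank1"]]
  df_res <- n - obs[["rank2"]]
  if (df_res < 1)
    stopf("no residual degrees of freedom; use a coarser nested factor")
  F_obs <- c(island = (obs[["ss_island"]] / df1) / (obs[["ss_res"]] / df_res),
             depth = (obs[["ss_depth"]] / df2) / (obs[["ss_res"]] / df_res))
  set.seed(seed)
  count <- c(island = 0L, depth = 0L)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    s <- stat(G[p, p])
    Fp <- c((s[["ss_island"]] / df1) / (s[["ss_res"]] / df_res),
            (s[["ss_depth"]] / df2) / (s[["ss_res"]] / df_res))
    count <- count + (Fp >= F_obs)
  }
  p_val <- (1 + count) / (1 + n_perm)
  tab <- data.frame(
    term = c("island", "depth_within_island", "residual", "total"),
    Df = c(df1, df2, df_res, n - 1),
    SumOfSqs = c(obs[["ss_island"]], obs[["ss_depth"]], obs[["ss_res"]],
                 SS_total),
    R2 = c(obs[["ss_island"]], obs[["ss_depth"]], obs[["ss_res"]],
           SS_total) / SS_total,
    F = c(F_obs, NA, NA),
    p = c(p_val, NA, NA))
  structure(list(tab = tab, n_perm = n_perm, seed = seed),
            class = "nested_permanova_fit")
}

#' @export
print.nested_permanova_fit <- function(x, ...) {
  cat("Nested PermANOVA: island + depth within island (sequential SS)\n")
  print(x$tab, row.names = FALSE, digits = 4)
  invisible(x)
}
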