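# Independent oracles used across tests.

# Top-down enumeration over all global alignments of two short strings,
# minimising (edits, columns) lexicographically. Written over suffixes,
# independently of the package's bottom-up kernel; edit distances are
# additionally cross-checked against utils::adist where used.
oracle_align <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    if (i > na && j > nb) {
      res <- c(0L, 0L)
    } else {
      cands <- list()
      if (i <= na && j <= nb) {
        mis <- as.integer(substr(a, i, i) != substr(b, j, j))
        cands <- c(cands, list(rec(i + 1, j + 1) + c(mis, 1L)))
      }
      if (i <= na) cands <- c(cands, list(rec(i + 1, j) + c(1L, 1L)))
      if (j <= nb) cands <- c(cands, list(rec(i, j + 1) + c(1L, 1L)))
      res <- cands[[1]]
      for (cc in cands)
        if (cc[1] < res[1] || (cc[1] == res[1] && cc[2] < res[2])) res <- cc
    }
    memo[[key]] <- res
    res
  }
  r <- rec(1, 1)
  list(edits = r[1], aln_len = r[2])
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Monte-Carlo rarefaction: mean richness over random subsamples without
# replacement, with its standard error.
mc_rarefaction <- function(counts, depth, n_draws = 1000) {
  reads <- rep(seq_along(counts), counts)
  rich <- vapply(seq_len(n_draws), function(i)
    length(unique(sample(reads, depth))), numeric(1))
  list(mean = mean(rich), se = sd(rich) / sqrt(n_draws))
}

# a small environmental fixture shared by several tests
make_fixture_study <- function(seed = 11) {
  simulate_study(seed = seed,
                 design = env_design(core_size = 20, zone_size = 10,
                                     island_size = 8,
                                     reads_per_sample = 2e4, seed = seed))
}

# binary presence matrix from an explicit membership assignment:
# `membership` is a list of character vectors of group labels, `samples`
# a named map group label -> sample id
presence_from_membership <- function(membership, samples) {
  m <- matrix(0L, length(samples), length(membership),
              dimnames = list(unname(samples),
                              sprintf("asv%04d", seq_along(membership))))
  for (a in seq_along(membership))
    m[unname(samples[membership[[a]]]), a] <- 1L
  m
}
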