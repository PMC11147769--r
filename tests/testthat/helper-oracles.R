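# Independent oracles kept deliberately separate from the package's own code
# paths: numeric root-finding on the sigmoid growth equation, and full
# hypergeometric enumeration for the two-sided Fisher test.

# fitness implied by (v0, v1, dt) found by brute-force root search on
# v(t) = 0.5 / (1 + A e^(-s t)) with A anchored at v0 — never uses the
# package's closed form
oracle_fitness <- function(v0, v1, dt) {
  A <- 1 / (2 * v0) - 1
  f <- function(s) 0.5 / (1 + A * exp(-s * dt)) - v1
  stats::uniroot(f, interval = c(-100, 100), tol = 1e-13)$root
}

# two-sided probability-based exact p for a 2x2 table: enumerate all tables
# with the observed margins via the hypergeometric distribution and sum the
# probabilities of tables no more probable than the observed one
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small deterministic genotype-matrix builder: clones given as list of
# genotype vectors with exact cell counts (no noise)
build_matrix <- function(clone_counts, genotypes, n_wt = 0, variant_ids = NULL) {
  rows <- list()
  for (i in seq_along(clone_counts)) {
    rows[[i]] <- matrix(rep(genotypes[[i]], clone_counts[i]),
                        nrow = clone_counts[i], byrow = TRUE)
  }
  if (n_wt > 0) {
    rows[[length(rows) + 1]] <- matrix(0L, n_wt, length(genotypes[[1]]))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- if (is.null(variant_ids)) paste0("V", seq_len(ncol(m))) else variant_ids
  rownames(m) <- sprintf("cell%04d", seq_len(nrow(m)))
  m
}
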