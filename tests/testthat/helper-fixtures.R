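# Fixtures are built in code; no data files.

# a tiny deterministic cohort for structural tests
tiny_cohort <- function(seed = 1L, n_per_group = c(SN = 4L, AST = 3L, MST = 4L),
                        n_genes = 60L, ...) {
  generate_cohort(synthetic_config(
    n_per_group = n_per_group, n_genes = n_genes, n_housekeeping = 5L,
    n_de_genes = 8L, n_signature_genes = 4L, seed = seed, ...))
}

# null cohort at full panel scale: no planted effects
null_cohort <- function(seed, n_genes = 770L) {
  generate_cohort(synthetic_config(
    n_genes = n_genes, n_de_genes = 0L, n_signature_genes = 0L, seed = seed))
}

# independent brute-force BH oracle: q_i = min over ranks k with
# p_(k) >= p_i of n * p_(k) / k, capped at 1
bh_brute <- function(p) {
  n <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    ks <- which(ps >= pi - 1e-15)
    min(1, min(n * ps[ks] / ks))
  }, 0)
}

# ordinary weighted two-sample t-statistic (independent of fit_contrast
# internals): WLS on the two-group design, no variance moderation
weighted_t_oracle <- function(x, w, g1_idx, g2_idx) {
  W1 <- sum(w[g1_idx]); W2 <- sum(w[g2_idx])
  m1 <- sum(w[g1_idx] * x[g1_idx]) / W1
  m2 <- sum(w[g2_idx] * x[g2_idx]) / W2
  rss <- sum(w[g1_idx] * (x[g1_idx] - m1)^2) +
    sum(w[g2_idx] * (x[g2_idx] - m2)^2)
  df <- length(g1_idx) + length(g2_idx) - 2
  s2 <- rss / df
  (m2 - m1) / sqrt(s2 * (1 / W1 + 1 / W2))
}

# random gene-set list over a cohort's genes
random_sets <- function(cohort, n_sets, size, seed) {
  ids <- cohort$gene_ids
  sets <- lapply(seq_len(n_sets), function(i) {
    set.seed(seed + i)
    sample(ids, size)
  })
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  sets
}
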