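# Independent brute-force oracles used across test files.  These follow the
# definitions literally and share no code with the implementation.

# quantile normalization: sort each column, average across columns per rank,
# map each value back to the reference value of its rank; tied values get
# the mean of the tied reference values.
oracle_quantile <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    ord <- order(m[, j])
    vals <- ref
    # assign by rank, then average within tied groups
    assigned <- numeric(nrow(m))
    assigned[ord] <- vals
    for (v in unique(m[, j])) {
      idx <- which(m[, j] == v)
      assigned[idx] <- mean(assigned[idx])
    }
    out[, j] <- assigned
  }
  out
}

# direction-symmetric max fold of a series relative to its first element
oracle_max_fold <- function(x) {
  f <- numeric(0)
  for (t in seq_along(x)[-1]) f <- c(f, max(x[t] / x[1], x[1] / x[t]))
  max(f)
}

# tiny deterministic two-line experiment from per-gene series lists; gene
# names are taken from the oncogene list
make_experiment <- function(oncogene, parental, time) {
  h <- do.call(rbind, oncogene)
  a <- do.call(rbind, parental)
  rownames(a) <- rownames(h)
  ts_experiment(parental = a, oncogene = h, time = time)
}

# a small noisy experiment for I/O round trips
tiny_sim <- function(seed = 99, n_genes = 30, sigma = 0.05) {
  simulate_experiment(synthetic_config(
    n_genes = n_genes, frac_oncogene_specific = 0.2,
    frac_shared_regulated = 0.2, noise_sigma = sigma, seed = seed))
}
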