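# Shared fixtures, built in code at test time.

# Small, fast synthetic gene for unit tests (the full-size defaults are used
# in the acceptance tests only).
small_dataset <- function(seed = 42L, length = 120L, n_pos = 25L, n_neg = 60L,
                          ...) {
  simulate_dataset(synthetic_spec(length = length, n_pos = n_pos,
                                  n_neg = n_neg, seed = seed, ...))
}

fast_config <- function(n_trees = 150L, ...) mova_config(n_trees = n_trees, ...)

# Stub backend: ignores the data, predicts a constant.
constant_backend <- function(value) {
  function(x, y01, seed) function(newx) rep(value, nrow(newx))
}

# Stub backend: deterministic monotone function of the x coordinate.
x_logistic_backend <- function(scale = 0.1) {
  function(x, y01, seed) function(newx) stats::plogis(scale * newx$x)
}

# Hand-rolled PDB ATOM line (independent of write_structure's formatting).
pdb_atom_line <- function(serial, atom, res3, resseq, x, y, z, b, chain = "A") {
  sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, atom, res3, chain, resseq, x, y, z, 1.00, b)
}

# Brute-force AUC oracle: explicit pair counting.
auc_oracle <- function(scores, labels01) {
  pos <- scores[labels01 == 1L]
  neg <- scores[labels01 == 0L]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden oracle: scan all observed thresholds, rule score >= t,
# smallest maximiser.
youden_oracle <- function(scores, labels01) {
  pos <- scores[labels01 == 1L]
  neg <- scores[labels01 == 0L]
  cand <- sort(unique(scores))
  best_t <- NA_real_
  best_j <- -Inf
  for (t in cand) {
    # exact integer form of J * (n_pos * n_neg), immune to float ties
    j <- sum(pos >= t) * length(neg) + sum(neg < t) * length(pos)
    if (j > best_j) {
      best_j <- j
      best_t <- t
    }
  }
  best_t
}

random_labels <- function(n, npos) {
  sample(rep(c(1L, 0L), c(npos, n - npos)))
}
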