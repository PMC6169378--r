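# Shared fixtures and independent oracles for the test suite.

# Write a small two-row STRUCTURE file and return its path.
write_structure_fixture <- function(lines) {
  path <- tempfile(fileext = ".str")
  writeLines(lines, path)
  path
}

# Independent triple-loop evaluation of the admixture-model log-likelihood,
# deliberately naive (no vectorization, no shared code with the package).
loglik_oracle <- function(counts, eta, p) {
  ll <- 0
  for (i in seq_len(nrow(eta))) {
    for (l in seq_along(counts)) {
      for (a in seq_len(ncol(counts[[l]]))) {
        n <- counts[[l]][i, a]
        if (n > 0) {
          mix <- 0
          for (k in seq_len(ncol(eta))) mix <- mix + eta[i, k] * p[[l]][k, a]
          ll <- ll + n * log(mix)
        }
      }
    }
  }
  ll
}

# Exhaustive grid search over the 3-state simplex (step `by`), maximizing
# sum_l log(B3 %*% delta); independent check on the simplex optimizer.
grid_oracle_3state <- function(B3, by = 0.01) {
  best <- -Inf; best_d <- NULL
  for (d7 in seq(0, 1, by = by)) {
    for (d8 in seq(0, 1 - d7, by = by)) {
      d <- c(d7, d8, 1 - d7 - d8)
      v <- as.vector(B3 %*% d)
      if (all(v > 0)) {
        ll <- sum(log(v))
        if (ll > best) { best <- ll; best_d <- d }
      }
    }
  }
  list(loglik = best, delta = best_d)
}

# Best column permutation match between an estimated and a true membership
# assignment (handles label switching); returns the mean agreement.
best_permutation_agreement <- function(assign_hat, assign_true, K) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  best <- 0
  for (pm in perms(seq_len(K)))
    best <- max(best, mean(pm[assign_hat] == assign_true))
  best
}

# Small deterministic panel used across I/O tests: 3 individuals, 2 loci,
# codes {101, 103, 105} at locus 1 and {7, 9} at locus 2; one missing.
make_toy_structure_file <- function() {
  write_structure_fixture(c(
    "ind1 101 7",
    "ind1 103 9",
    "ind2 103 7",
    "ind2 103 7",
    "ind3 105 -9",
    "ind3 101 -9"))
}
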