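# exact null distributions of |Spearman rho| for untied samples, cached per n
spearman_null_env <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# sorted (descending) |rho| values over all n! rank permutations
spearman_null_absr <- function(n) {
  key <- as.character(n)
  if (!is.null(spearman_null_env[[key]])) return(spearman_null_env[[key]])
  perms <- all_permutations(n)
  s <- rowSums(sweep(perms, 2, seq_len(n))^2)
  r <- 1 - 6 * s / (n * (n^2 - 1))
  absr <- sort(abs(r), decreasing = TRUE)
  spearman_null_env[[key]] <- absr
  absr
}

# exact two-sided p for |rho| = r at sample size n (no ties)
spearman_exact_p <- function(r, n) {
  absr <- spearman_null_absr(n)
  sum(absr >= abs(r) - 1e-12) / length(absr)
}

# t-approximation two-sided p (mid-rank ties handled upstream by cor)
spearman_approx_p <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}
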