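# small builders shared across test files

toy_counts <- function(m, taxa = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- taxa %||% sprintf("taxon%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_counts <- function(n_taxa, n_samples, lambda = 20) {
  toy_counts(matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa))
}

# two Gaussian classes, n per class, p features, `shift` sd in the first
# n_informative features
two_class_data <- function(n_per_class = 8, p = 20, shift = 3,
                           n_informative = 5) {
  x <- matrix(stats::rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  y <- rep(c(-1, 1), each = n_per_class)
  x[y == 1, seq_len(n_informative)] <- x[y == 1, seq_len(n_informative)] + shift
  list(x = x, y = y)
}

# a small (fast) study design that keeps the default effect/coupling layout
small_design <- function(...) {
  simulation_design(n_subjects_per_group = 4L, n_taxa = 60L,
                    library_size_log_mean = log(5000), ...)
}

# single-Lorentzian spectra builder on a uniform grid
peak_spectra <- function(n_samples, center = 3, gamma = 0.01,
                         ppm = seq(0.5, 8.5, by = 0.001), heights = NULL) {
  heights <- heights %||% rep(1, n_samples)
  ints <- t(sapply(heights, function(h)
    h * (gamma / pi) / ((ppm - center)^2 + gamma^2)))
  spectra_matrix(ppm, ints)
}
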