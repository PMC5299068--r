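#' Deterministic LDA effect scores for differentially abundant taxa
#'
#' A simplified, deterministic variant of the LEfSe procedure for two-class
#' comparisons. Features are scaled to relative abundance times 1e6;
#' features passing a two-sided Mann-Whitney test at `alpha` enter a Fisher
#' linear discriminant with diagonal-regularized pooled within-class
#' covariance. The per-feature effect size combines the univariate
#' class-mean difference with the feature's share of the discriminant-axis
#' separation: `effect_j = (|delta_j| + |w_j * Delta|) / 2`, where
#' `delta_j` is the class-mean difference of feature j, `w_j` the
#' unit-normalized discriminant coefficient and `Delta` the class-mean
#' difference of the projections. The reported score is
#' `log10(1 + effect)`; a feature is flagged when its p-value is below
#' `alpha` and its score reaches `cutoff` (3.0, the conventional screen
#' between 2.0 and 4.0). No bootstrap resampling or subclass logic is
#' used, so results are reproducible without a seed.
#'
#' @param counts OTU count matrix (taxa x samples).
#' @param groups Two-group factor (one level pair; more groups -> error,
#'   call pairwise).
#' @param alpha Mann-Whitney significance level (default 0.05).
#' @param cutoff LDA score cutoff on the log10 scale (default 3.0).
#' @return Data frame per taxon: `taxon`, `p_value`, `lda_score`,
#'   `enriched_group`, `passes_cutoff`.
#' @export
lefse_score <- function(counts, groups, alpha = 0.05, cutoff = 3.0) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L)
    abort("lefse_score compares exactly 2 groups (got %d); call pairwise",
          nlevels(groups))
  x <- rel_abundance(counts) * 1e6          # features x samples, scaled units
  g1 <- levels(groups)[1L]; g2 <- levels(groups)[2L]
  i1 <- which(groups == g1); i2 <- which(groups == g2)
  pvals <- apply(x, 1, function(v)
    suppressWarnings(stats::wilcox.test(v[i1], v[i2])$p.value))
  delta <- rowMeans(x[, i1, drop = FALSE]) - rowMeans(x[, i2, drop = FALSE])

  score <- numeric(nrow(x))
  sig <- which(pvals < alpha)
  if (length(sig) > 0L) {
    xs <- t(x[sig, , drop = FALSE])          # samples x significant features
    mu1 <- colMeans(xs[i1, , drop = FALSE])
    mu2 <- colMeans(xs[i2, , drop = FALSE])
    cw <- (crossprod(sweep(xs[i1, , drop = FALSE], 2, mu1)) +
           crossprod(sweep(xs[i2, , drop = FALSE], 2, mu2))) /
      (nrow(xs) - 2)
    ridge <- 1e-3 * mean(diag(cw)) + 1e-12   # keeps the solve well-posed
    w <- solve(cw + diag(ridge, ncol(cw)), mu1 - mu2)
    w <- w / sqrt(sum(w^2))
    Delta <- sum(w * (mu1 - mu2))            # projection mean difference
    effect <- (abs(delta[sig]) + abs(w * Delta)) / 2
    score[sig] <- log10(1 + effect)
  }
  data.frame(taxon = rownames(counts), p_value = pvals, lda_score = score,
             enriched_group = ifelse(delta >= 0, g1, g2),
             passes_cutoff = pvals < alpha & score >= cutoff,
             row.names = NULL)
}
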