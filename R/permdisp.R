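#' PERMDISP: permutation test for homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by principal-coordinate analysis, keeping the
#' axes of positive and negative eigenvalues separately, and computes each
#' sample's distance to its group centroid with the negative-eigenvalue
#' correction (squared real-part distance minus squared imaginary-part
#' distance, floored at zero before the square root). Group differences in
#' these centroid distances are tested with the one-way ANOVA F statistic;
#' the null distribution comes from permuting the least-squares residuals
#' of the centroid distances across samples.
#'
#' @param d Symmetric distance matrix.
#' @param groups Group labels, >= 2 groups with >= 2 samples each.
#' @param n_permutations Number of residual permutations (default 999).
#' @param seed Integer seed.
#' @return List with `distances` (per-sample distance to group centroid),
#'   `group_means`, `f`, `t` (NA unless two groups) and `p_perm`.
#' @export
permdisp <- function(d, groups, n_permutations = 999L, seed = 1L) {
  ck <- check_dist_groups(d, groups)
  d <- ck$d; groups <- ck$groups
  n <- nrow(d)
  g <- -0.5 * d^2
  cmat <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(cmat %*% g %*% cmat, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values), 1) * 1e-10
  lam <- e$values[keep]
  vec <- e$vectors[, keep, drop = FALSE]
  axes <- sweep(vec, 2, sqrt(abs(lam)), "*")
  pos <- lam > 0

  z <- numeric(n)
  for (gr in levels(groups)) {
    idx <- which(groups == gr)
    cen <- colMeans(axes[idx, , drop = FALSE])
    dev <- sweep(axes[idx, , drop = FALSE], 2, cen)^2
    d2 <- rowSums(dev[, pos, drop = FALSE]) -
      rowSums(dev[, !pos, drop = FALSE])
    z[idx] <- sqrt(pmax(0, d2))
  }

  anova_f <- function(y, grp) {
    gm <- tapply(y, grp, mean)
    sizes <- tabulate(grp)
    ssb <- sum(sizes * (gm - mean(y))^2)
    ssw <- sum((y - gm[grp])^2)
    msw <- ssw / (length(y) - nlevels(grp))
    if (msw > 0) (ssb / (nlevels(grp) - 1)) / msw
    else if (ssb > 1e-14) Inf else 0
  }
  f_obs <- anova_f(z, groups)
  resid <- z - tapply(z, groups, mean)[groups]
  set.seed(derive_seed(seed, "permdisp"))
  b <- 0L
  for (i in seq_len(n_permutations)) {
    if (anova_f(resid[sample.int(n)], groups) >= f_obs - 1e-12) b <- b + 1L
  }
  list(distances = stats::setNames(z, rownames(d)),
       group_means = tapply(z, groups, mean),
       f = f_obs,
       t = if (nlevels(groups) == 2L) sqrt(f_obs) else NA_real_,
       p_perm = (1 + b) / (1 + n_permutations))
}
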