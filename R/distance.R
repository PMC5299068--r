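#' Bray-Curtis distances on square-root relative abundances
#'
#' Transforms counts to per-sample relative abundances, square-root
#' transforms them, and computes pairwise Bray-Curtis dissimilarities
#' d(u, v) = sum|x_u - x_v| / sum(x_u + x_v). The percent similarity used in
#' community-ecology reporting is `100 * (1 - d)`.
#'
#' @param counts OTU count matrix (taxa x samples, >= 2 samples, positive
#'   column sums).
#' @return Symmetric samples x samples distance matrix (zero diagonal,
#'   entries in `[0, 1]`).
#' @export
bray_curtis_sqrt <- function(counts) {
  if (ncol(counts) < 2L) abort("need >= 2 samples")
  x <- sqrt(rel_abundance(counts))
  d <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  diag(d) <- 0
  dimnames(d) <- list(colnames(counts), colnames(counts))
  d
}

#' Percent similarity between two groups from a distance matrix
#'
#' Mean over all between-group pairs of `100 * (1 - d)`.
#'
#' @param d Symmetric distance matrix.
#' @param groups Group labels (one per sample).
#' @param group_a,group_b The two groups to compare.
#' @return Mean percent similarity (scalar).
#' @export
mean_similarity <- function(d, groups, group_a, group_b) {
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (length(ia) == 0L || length(ib) == 0L) abort("empty group")
  100 * (1 - mean(d[ia, ib]))
}

# validate a distance matrix + group vector pair
check_dist_groups <- function(d, groups, min_per_group = 2L) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12)
    abort("distance matrix must be symmetric")
  if (length(groups) != nrow(d))
    abort("groups length (%d) != number of samples (%d)",
          length(groups), nrow(d))
  groups <- factor(groups)
  if (nlevels(groups) < 2L) abort("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < min_per_group))
    abort("group '%s' has < %d samples",
          names(sizes)[sizes < min_per_group][1L], min_per_group)
  list(d = d, groups = droplevels(groups))
}
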