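# one-way pseudo-F from a squared-distance matrix and a grouping;
# Anderson's partition: SS_total = sum_{i<j} d2 / N,
# SS_within = sum_g sum_{i<j in g} d2 / n_g
pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- nlevels(groups)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_b <- ss_tot - ss_w
  ms_b <- ss_b / (a - 1)
  ms_w <- ss_w / (n - a)
  f <- if (ms_w > 0) ms_b / ms_w else if (ss_b > 1e-14) Inf else 0
  list(f = f, ss_between = ss_b, ss_within = ss_w, ms_between = ms_b,
       ms_within = ms_w)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' partitions the total sum of squared inter-point distances into between-
#' and within-group components; significance comes from permuting sample
#' labels. For the one-way designs handled here, permutation of raw labels
#' coincides with permutation of residuals under a reduced model with no
#' covariates. The permutation p-value uses the `(1 + b) / (1 + m)`
#' estimator so it is never zero. For a two-group (pairwise) comparison the
#' conventional t statistic `sqrt(F)` is reported, together with the square
#' root of the estimated component of variation,
#' `sqrt(max(0, (MS_between - MS_within) / n_bar))`.
#'
#' @param d Symmetric distance matrix.
#' @param groups Group labels, >= 2 groups with >= 2 samples each.
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed Integer seed.
#' @return List with `pseudo_f`, `t` (NA unless two groups), `p_perm`,
#'   `sqrt_ecv`, `n_permutations_used` and the sum-of-squares partition.
#' @export
permanova <- function(d, groups, n_permutations = 9999L, seed = 1L) {
  ck <- check_dist_groups(d, groups)
  d2 <- ck$d^2
  groups <- ck$groups
  obs <- pseudo_f(d2, groups)
  set.seed(derive_seed(seed, "permanova"))
  n <- nrow(d2)
  b <- 0L
  for (i in seq_len(n_permutations)) {
    fp <- pseudo_f(d2, groups[sample.int(n)])$f
    if (fp >= obs$f - 1e-12) b <- b + 1L
  }
  nbar <- mean(table(groups))
  list(pseudo_f = obs$f,
       t = if (nlevels(groups) == 2L) sqrt(obs$f) else NA_real_,
       p_perm = (1 + b) / (1 + n_permutations),
       sqrt_ecv = sqrt(max(0, (obs$ms_between - obs$ms_within) / nbar)),
       ss_between = obs$ss_between, ss_within = obs$ss_within,
       n_permutations_used = as.integer(n_permutations))
}

#' Pairwise PERMANOVA over all group pairs
#'
#' @inheritParams permanova
#' @return Data frame with one row per pair: `group_a`, `group_b`, `t`,
#'   `pseudo_f`, `p_perm`.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 9999L, seed = 1L) {
  groups <- factor(groups)
  lv <- levels(droplevels(groups))
  pairs <- utils::combn(lv, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- groups %in% pairs[, i]
    r <- permanova(as.matrix(d)[sel, sel], droplevels(groups[sel]),
                   n_permutations, derive_seed(seed, paste0("pair", i)))
    data.frame(group_a = pairs[1L, i], group_b = pairs[2L, i], t = r$t,
               pseudo_f = r$pseudo_f, p_perm = r$p_perm)
  })
  do.call(rbind, out)
}
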