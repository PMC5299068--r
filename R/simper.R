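#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' Decomposes the mean between-group Bray-Curtis dissimilarity (on
#' square-root relative abundances, as in [bray_curtis_sqrt()]) into
#' additive per-taxon contributions: for each between-group sample pair the
#' taxon term is `|x_u - x_v| / sum(x_u + x_v)`, and contributions average
#' over all pairs. The per-taxon contributions sum exactly to the mean
#' between-group dissimilarity.
#'
#' @param counts OTU count matrix (taxa x samples).
#' @param groups Group labels (one per sample).
#' @param group_a,group_b The two groups to compare (both non-empty).
#' @return Data frame sorted by decreasing contribution with columns
#'   `taxon`, `contribution`, `percent`, `cumulative_percent`.
#' @export
simper <- function(counts, groups, group_a, group_b) {
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) == 0L) abort("group '%s' is empty", group_a)
  if (length(ib) == 0L) abort("group '%s' is empty", group_b)
  x <- sqrt(rel_abundance(counts))
  contrib <- numeric(nrow(counts))
  for (u in ia) for (v in ib) {
    denom <- sum(x[, u] + x[, v])
    contrib <- contrib + abs(x[, u] - x[, v]) / denom
  }
  contrib <- contrib / (length(ia) * length(ib))
  out <- data.frame(taxon = rownames(counts), contribution = contrib,
                    row.names = NULL)
  out <- out[order(-out$contribution, out$taxon), ]
  total <- sum(out$contribution)
  out$percent <- if (total > 0) 100 * out$contribution / total else 0
  out$cumulative_percent <- cumsum(out$percent)
  rownames(out) <- NULL
  out
}
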