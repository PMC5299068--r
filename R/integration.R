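#' Volcano table: fold changes and FDR-adjusted significance
#'
#' For each feature (metabolite or bucket), the log2 fold change of the
#' treatment-group mean against the control-group mean, a two-sided
#' Mann-Whitney p-value, its Benjamini-Hochberg q-value over all features,
#' and a significance flag requiring both a 2-fold change and q at or
#' below 0.05. Features whose group mean is zero or negative get an NA
#' fold change and are never flagged. A Welch t-test is available behind
#' `test = "t"`.
#'
#' @param features Numeric matrix, samples x features (non-negative).
#' @param groups Two-level grouping (one per sample, >= 3 per group).
#' @param control Level treated as the reference (denominator).
#' @param fc_threshold Fold-change gate on the natural scale (default 2).
#' @param q_threshold FDR gate (default 0.05).
#' @param test `"mann-whitney"` (default) or `"t"`.
#' @return Data frame per feature: `feature`, `log2_fc`, `p_value`, `q_value`,
#'   `significant`.
#' @export
volcano_table <- function(features, groups, control = "control",
                          fc_threshold = 2.0, q_threshold = 0.05,
                          test = c("mann-whitney", "t")) {
  test <- match.arg(test)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L) abort("volcano_table needs exactly 2 groups")
  if (!control %in% levels(groups))
    abort("control level '%s' not among groups", control)
  treat <- setdiff(levels(groups), control)
  ic <- which(groups == control); it <- which(groups == treat)
  if (length(ic) < 3L || length(it) < 3L) abort("each group needs >= 3 samples")
  features <- as.matrix(features)
  mc <- colMeans(features[ic, , drop = FALSE])
  mt <- colMeans(features[it, , drop = FALSE])
  log2_fc <- ifelse(mc > 0 & mt > 0, log2(mt / mc), NA_real_)
  p <- apply(features, 2, function(v) {
    if (test == "mann-whitney")
      suppressWarnings(stats::wilcox.test(v[it], v[ic])$p.value)
    else stats::t.test(v[it], v[ic])$p.value
  })
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature = colnames(features) %||%
               paste0("feature", seq_along(p)),
             log2_fc = log2_fc, p_value = p, q_value = q,
             significant = !is.na(log2_fc) &
               abs(log2_fc) >= log2(fc_threshold) & q <= q_threshold,
             row.names = NULL)
}

#' Gate taxa and metabolites into the correlation analysis
#'
#' Taxa: the minimal prefix of the SIMPER ranking whose cumulative
#' contribution reaches `cum_cutoff` (70% by default). Metabolites: the
#' features whose volcano FDR-adjusted q-value is at or below `p_cutoff`.
#' Empty selections are allowed (with a warning).
#'
#' @param simper_table A [simper()] result (sorted descending).
#' @param volcano A [volcano_table()] result.
#' @param cum_cutoff Cumulative-contribution cutoff in `[0, 1]`.
#' @param p_cutoff Metabolite significance cutoff on q.
#' @return List with `taxa` and `metabolites` (character vectors).
#' @export
select_features <- function(simper_table, volcano, cum_cutoff = 0.70,
                            p_cutoff = 0.05) {
  cum <- simper_table$cumulative_percent / 100
  n_taxa <- if (any(cum >= cum_cutoff - 1e-12))
    which(cum >= cum_cutoff - 1e-12)[1L] else nrow(simper_table)
  taxa <- as.character(simper_table$taxon[seq_len(n_taxa)])
  metabolites <- as.character(
    volcano$feature[!is.na(volcano$q_value) & volcano$q_value <= p_cutoff])
  if (length(metabolites) == 0L)
    warning("no metabolite passed the q-value gate", call. = FALSE)
  if (length(taxa) == 0L) warning("no taxon selected", call. = FALSE)
  list(taxa = taxa, metabolites = metabolites)
}

#' Thresholded Spearman correlation matrix of taxa versus metabolites
#'
#' Spearman rank correlation (mid-rank ties) of every taxon against every
#' metabolite across the shared samples. P-values are exact (full
#' permutation enumeration) for n at most 9 with untied data, otherwise by
#' the t-distribution approximation. Benjamini-Hochberg adjustment is
#' applied jointly over all defined cells; the significance mask requires
#' |r| > 0.75 and q < 0.01. Constant vectors give NA cells, excluded from
#' the adjustment family.
#'
#' @param taxa_abund Numeric matrix, samples x taxa.
#' @param metab Numeric matrix, samples x metabolites (same samples).
#' @param r_threshold Absolute-correlation gate (default 0.75).
#' @param q_threshold FDR gate (default 0.01).
#' @return List of class `"correlation_matrix"` with matrices `r`, `p`,
#'   `q`, `mask` (taxa x metabolites).
#' @export
spearman_matrix <- function(taxa_abund, metab, r_threshold = 0.75,
                            q_threshold = 0.01) {
  taxa_abund <- as.matrix(taxa_abund); metab <- as.matrix(metab)
  if (nrow(taxa_abund) != nrow(metab))
    abort("taxa and metabolite matrices must share samples")
  n <- nrow(taxa_abund)
  if (n < 5L) abort("need >= 5 samples")
  r <- suppressWarnings(stats::cor(taxa_abund, metab, method = "spearman"))
  const_t <- apply(taxa_abund, 2, function(v) length(unique(v)) == 1L)
  const_m <- apply(metab, 2, function(v) length(unique(v)) == 1L)
  r[const_t, ] <- NA
  r[, const_m] <- NA
  tied_t <- apply(taxa_abund, 2, anyDuplicated) > 0
  tied_m <- apply(metab, 2, anyDuplicated) > 0
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  use_exact <- n <= 9L
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
    if (is.na(r[i, j])) next
    p[i, j] <- if (use_exact && !tied_t[i] && !tied_m[j])
      spearman_exact_p(r[i, j], n)
    else spearman_approx_p(r[i, j], n)
  }
  q <- p
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  mask <- !is.na(r) & abs(r) > r_threshold & q < q_threshold
  structure(list(r = r, p = p, q = q, mask = mask,
                 r_threshold = r_threshold, q_threshold = q_threshold),
            class = "correlation_matrix")
}

#' Ward-linkage leaf order for heatmap axes
#'
#' Agglomerative clustering (Ward's method on Euclidean distances by
#' default; Bray-Curtis available for taxon abundance heatmaps) of the row
#' or column vectors of a matrix, returning the deterministic dendrogram
#' leaf order.
#'
#' @param m Numeric matrix without NAs.
#' @param axis `"rows"` or `"cols"`.
#' @param distance `"euclidean"` (default) or `"bray"`.
#' @return Integer permutation of the axis indices.
#' @export
ward_order <- function(m, axis = c("rows", "cols"),
                       distance = c("euclidean", "bray")) {
  axis <- match.arg(axis); distance <- match.arg(distance)
  v <- if (axis == "rows") as.matrix(m) else t(as.matrix(m))
  if (anyNA(v)) abort("NA values present; impute or exclude before ordering")
  if (nrow(v) < 2L) abort("need >= 2 items to order")
  d <- if (distance == "euclidean") stats::dist(v)
       else vegan::vegdist(v, method = "bray")
  stats::hclust(d, method = "ward.D2")$order
}
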