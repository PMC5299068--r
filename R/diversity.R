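#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement (hypergeometric
#' draw) so every column sums exactly to `depth`, mirroring the common
#' practice of subsampling all libraries to the smallest read depth.
#'
#' @param counts OTU count matrix (taxa x samples).
#' @param depth Target depth; default = minimum column sum.
#' @param seed Integer seed.
#' @return Rarefied count matrix with identical dimensions.
#' @export
rarefy_counts <- function(counts, depth = NULL, seed = 1L) {
  cs <- colSums(counts)
  if (is.null(depth) || is.na(depth)) depth <- min(cs)
  short <- which(cs < depth)
  if (length(short) > 0L)
    abort("sample '%s' has only %d reads (< depth %d)",
          colnames(counts)[short[1L]], cs[short[1L]], depth)
  set.seed(derive_seed(seed, "rarefy"))
  out <- counts
  for (j in seq_len(ncol(counts))) {
    reads <- rep.int(seq_len(nrow(counts)), counts[, j])
    keep <- sample(reads, depth)
    out[, j] <- tabulate(keep, nbins = nrow(counts))
  }
  out
}

#' Per-sample alpha diversity
#'
#' Computes taxon richness S (taxa with nonzero count), the Shannon-Wiener
#' index H = -sum p log p (natural log), and the Simpson diversity index
#' 1 - D = 1 - sum p^2, from per-sample relative abundances.
#'
#' @param counts OTU count matrix (taxa x samples) with positive column sums.
#' @return Data frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson` (the 1 - D form).
#' @export
alpha_diversity <- function(counts) {
  p <- rel_abundance(counts)
  data.frame(
    sample_id = colnames(counts),
    richness = colSums(counts > 0),
    shannon = apply(p, 2, function(q) { q <- q[q > 0]; -sum(q * log(q)) }),
    simpson = 1 - colSums(p^2),
    row.names = NULL
  )
}
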