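#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Minimizes Kruskal stress-1 by monotone regression of configuration
#' distances on dissimilarity ranks (vegan's `monoMDS`, global model,
#' Kruskal's primary tie treatment). The first restart starts from the
#' metric principal-coordinate embedding; the remaining restarts use random
#' configurations. The best (lowest-stress) solution is returned, centered
#' and rotated to its principal axes.
#'
#' @param d Symmetric distance matrix.
#' @param k Number of ordination axes (default 2, must be < n).
#' @param n_restarts Number of starts including the metric start (default 20).
#' @param max_iter,tol Iteration cap and convergence tolerance per start.
#' @param seed Integer seed for the random starts.
#' @return List with `points` (n x k coordinate matrix) and `stress`
#'   (Kruskal stress-1 in `[0, 1]`).
#' @export
nmds <- function(d, k = 2L, n_restarts = 20L, max_iter = 500L,
                 tol = 1e-7, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) abort("k (%d) must be smaller than the number of samples (%d)",
                    k, n)
  dd <- stats::as.dist(d)
  set.seed(derive_seed(seed, "nmds"))
  init <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(init) < k) init <- cbind(init, matrix(0, n, k - ncol(init)))
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    y0 <- if (r == 1L) init else matrix(stats::rnorm(n * k), n, k)
    fit <- vegan::monoMDS(dd, y = y0, k = k, model = "global",
                          maxit = max_iter, smin = 1e-6, sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  pts <- pts %*% svd(pts)$v      # rotate to principal axes
  dimnames(pts) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  list(points = pts, stress = best$stress)
}
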