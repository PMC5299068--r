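#' Exclude chemical-shift regions from spectra
#'
#' Removes spectral points inside any of the given open ppm intervals. The
#' defaults drop the noise regions below 0.5 and above 8.5 ppm, the water
#' peak (4.7--4.9 ppm) and the TSP reference signal around 0 ppm.
#'
#' @param spec A [spectra_matrix()].
#' @param regions List of length-2 numeric vectors `(lo, hi)`; points with
#'   `lo < ppm < hi` are removed.
#' @return A [spectra_matrix()] restricted to the retained axis, with the
#'   excluded regions recorded in the `excluded` attribute.
#' @export
exclude_regions <- function(spec,
                            regions = list(c(-Inf, 0.5), c(8.5, Inf),
                                           c(4.7, 4.9), c(-0.05, 0.05))) {
  drop <- rep(FALSE, length(spec$ppm))
  for (r in regions) drop <- drop | (spec$ppm > r[1L] & spec$ppm < r[2L])
  if (all(drop)) abort("exclusion regions cover the whole axis")
  out <- spectra_matrix(spec$ppm[!drop],
                        spec$intensities[, !drop, drop = FALSE])
  attr(out, "excluded") <- regions
  out
}

# split a (possibly gapped) ppm axis into runs of contiguous points
contiguous_runs <- function(ppm) {
  step <- stats::median(diff(ppm))
  breaks <- which(diff(ppm) > 1.5 * step)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(ppm))
  Map(seq.int, starts, ends)
}

# shift a vector right by s points (s may be negative), edge-padded
shift_vec <- function(v, s) {
  n <- length(v)
  if (s == 0) v
  else if (s > 0) c(rep(v[1L], s), v[seq_len(n - s)])
  else c(v[(1 - s):n], rep(v[n], -s))
}

#' Segment-wise spectral alignment against the median spectrum
#'
#' icoshift-style correction of small chemical-shift differences: the
#' target is the pointwise median spectrum; each spectrum is split into
#' fixed-width segments and each segment is shifted by the integer point
#' offset (bounded by `max_shift_ppm`) that maximizes its cross-correlation
#' with the target segment. Only whole-point shifts are applied (no
#' sub-point interpolation) and gaps are filled with segment-edge values.
#' Ties in the correlation go to the smallest |offset|, then to the more
#' negative one.
#'
#' @param spec A [spectra_matrix()].
#' @param segment_width_ppm Segment width (default 0.1 ppm).
#' @param max_shift_ppm Maximum correction (default 0.02 ppm; must be
#'   smaller than the segment width).
#' @return A [spectra_matrix()] with aligned intensities; the applied
#'   per-sample, per-segment offsets (points) are in the `shifts` attribute.
#' @export
align_spectra <- function(spec, segment_width_ppm = 0.1,
                          max_shift_ppm = 0.02) {
  step <- stats::median(diff(spec$ppm))
  seg_pts <- max(1L, round(segment_width_ppm / step))
  max_pts <- round(max_shift_ppm / step)
  if (seg_pts < 3L) abort("segment narrower than 3 points")
  if (max_pts >= seg_pts) abort("max_shift must be smaller than segment width")
  target <- apply(spec$intensities, 2, stats::median)
  out <- spec$intensities
  shifts_rec <- list()
  for (run in contiguous_runs(spec$ppm)) {
    n_seg <- max(1L, floor(length(run) / seg_pts))
    bounds <- floor(seq(0L, length(run), length.out = n_seg + 1L))
    for (s in seq_len(n_seg)) {
      idx <- run[(bounds[s] + 1L):bounds[s + 1L]]
      tseg <- target[idx]
      cand <- (-max_pts):max_pts
      cand <- cand[order(abs(cand), cand)]    # deterministic tie preference
      for (i in seq_len(nrow(out))) {
        seg <- spec$intensities[i, idx]
        # normalized cross-correlation: plain dot products reward edge
        # padding on monotone segments, cosine similarity does not
        cc <- vapply(cand, function(s0) {
          sh <- shift_vec(seg, s0)
          nrm <- sqrt(sum(sh^2))
          if (nrm == 0) 0 else sum(sh * tseg) / nrm
        }, numeric(1))
        best <- cand[which.max(cc)]
        out[i, idx] <- shift_vec(seg, best)
        shifts_rec[[length(shifts_rec) + 1L]] <-
          c(sample = i, segment_start = idx[1L], offset = best)
      }
    }
  }
  res <- spectra_matrix(spec$ppm, out)
  attr(res, "shifts") <- do.call(rbind, shifts_rec)
  res
}

#' Adaptive bucketing with a minimum bin width
#'
#' Divides the retained axis into buckets of at least `min_width_ppm`,
#' starting from uniform boundaries and relocating each interior boundary
#' to the local minimum of the mean spectrum within half a bucket width,
#' subject to all widths staying at or above the minimum (boundaries in
#' low-signal valleys avoid splitting peaks across buckets). Bucket values
#' are trapezoidal integrals, so the total integral of each spectrum is
#' conserved exactly.
#'
#' @param spec A [spectra_matrix()] (possibly with excluded gaps).
#' @param min_width_ppm Minimum bucket width (default 0.005 ppm).
#' @return List of class `"bucketed_matrix"`: `edges` (data frame `ppm_lo`,
#'   `ppm_hi`), `intensities` (samples x buckets), `excluded` provenance.
#' @export
adaptive_bucket <- function(spec, min_width_ppm = 0.005) {
  step <- stats::median(diff(spec$ppm))
  min_pts <- max(1L, ceiling(min_width_ppm / step - 1e-9))
  mean_spec <- colMeans(spec$intensities)
  half <- floor(min_pts / 2)
  edges <- list(); vals <- list()
  for (run in contiguous_runs(spec$ppm)) {
    if (length(run) < min_pts + 1L)
      abort("retained axis segment shorter than one bucket")
    n_b <- floor((length(run) - 1L) / min_pts)
    init <- 1L + min_pts * seq_len(n_b - 1L)      # interior boundaries (local)
    bpos <- integer(0)
    prev <- 1L
    for (b in init) {
      lo <- max(prev + min_pts, b - half)
      hi <- min(b + half, length(run) - min_pts)
      if (lo > hi) next
      win <- lo:hi
      rel <- win[which.min(mean_spec[run[win]])]
      bpos <- c(bpos, rel)
      prev <- rel
    }
    cuts <- unique(c(1L, bpos, length(run)))
    for (j in seq_len(length(cuts) - 1L)) {
      sel <- run[cuts[j]:cuts[j + 1L]]
      edges[[length(edges) + 1L]] <- c(spec$ppm[sel[1L]],
                                       spec$ppm[sel[length(sel)]])
      vals[[length(vals) + 1L]] <-
        apply(spec$intensities[, sel, drop = FALSE], 1,
              function(y) trapz(spec$ppm[sel], y))
    }
  }
  edges <- do.call(rbind, edges)
  intens <- do.call(cbind, vals)
  colnames(intens) <- sprintf("bucket_%.4f", (edges[, 1L] + edges[, 2L]) / 2)
  rownames(intens) <- spec$sample_ids
  structure(list(edges = data.frame(ppm_lo = edges[, 1L],
                                    ppm_hi = edges[, 2L]),
                 intensities = intens,
                 excluded = attr(spec, "excluded")),
            class = "bucketed_matrix")
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution: each sample is first normalized to unit
#' total integral, then divided by the median of its bucketwise quotients
#' against a reference spectrum (default: the median of the
#' integral-normalized samples). The stored `norm_factors` (total integral
#' times quotient, relative to the cohort) are proportional to the
#' underlying dilution factors; the operation is idempotent.
#'
#' @param bucketed A [adaptive_bucket()] result (or any samples x features
#'   matrix wrapped in one).
#' @param reference Optional reference spectrum (defaults to the median
#'   spectrum); must be positive on at least half the buckets.
#' @return The input with normalized `intensities` plus per-sample
#'   `quotients` and `norm_factors`.
#' @export
pqn_normalize <- function(bucketed, reference = NULL) {
  x <- bucketed$intensities
  totals <- rowSums(x)
  if (any(totals <= 0))
    abort("sample '%s' has zero total integral",
          rownames(x)[which(totals <= 0)[1L]])
  xin <- sweep(x, 1, totals, "/")
  ref <- reference %||% apply(xin, 2, stats::median)
  if (mean(ref > 0) < 0.5)
    abort("reference spectrum must be positive on >= 50%% of buckets")
  pos <- ref > 0
  q <- apply(xin, 1, function(v) stats::median(v[pos] / ref[pos]))
  bucketed$intensities <- sweep(xin, 1, q, "/")
  bucketed$quotients <- stats::setNames(q, rownames(x))
  bucketed$norm_factors <- stats::setNames(totals * q, rownames(x))
  bucketed
}

#' Pareto scaling
#'
#' Mean-centers each column and divides by the square root of its sample
#' standard deviation (n - 1 denominator), the usual compromise between
#' unit-variance and no scaling for spectral features. Constant columns are
#' centered, left unscaled and flagged.
#'
#' @param m Numeric matrix, samples x features (>= 2 samples).
#' @return List of class `"scaled_matrix"`: `data`, `center`, `scale`
#'   (the sqrt-sd divisors), `constant` (logical flags).
#' @export
pareto_scale <- function(m) {
  if (is.list(m) && !is.null(m$intensities)) m <- m$intensities
  if (nrow(m) < 2L) abort("need >= 2 samples")
  ctr <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  const <- sds <= 0
  scl <- ifelse(const, 1, sqrt(sds))
  structure(list(data = sweep(sweep(m, 2, ctr), 2, scl, "/"),
                 center = ctr, scale = scl, constant = const),
            class = "scaled_matrix")
}
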