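#' Construct a 1D spectra matrix
#'
#' Canonical in-memory container for a set of 1D NMR spectra on a shared
#' chemical-shift axis. The axis is always stored ascending; writers emit
#' the conventional descending-ppm orientation.
#'
#' @param ppm Strictly increasing numeric vector of chemical shifts (ppm).
#' @param intensities Numeric matrix, samples x points, all finite.
#' @return An object of class `"spectra_matrix"`.
#' @export
spectra_matrix <- function(ppm, intensities) {
  if (!is.matrix(intensities)) intensities <- rbind(intensities)
  if (length(ppm) != ncol(intensities))
    abort("ppm length (%d) != number of spectral points (%d)",
          length(ppm), ncol(intensities))
  if (any(diff(ppm) <= 0)) abort("ppm not strictly monotone")
  if (any(!is.finite(intensities))) {
    bad <- which(!is.finite(intensities), arr.ind = TRUE)[1L, ]
    abort("non-finite intensity at sample %s, ppm %.4f",
          rownames(intensities)[bad[1L]] %||% bad[1L], ppm[bad[2L]])
  }
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("sample", seq_len(nrow(intensities)))
  structure(list(ppm = as.numeric(ppm), intensities = intensities,
                 sample_ids = rownames(intensities)),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("spectra_matrix: %d samples, %d points, ppm [%.3f, %.3f]\n",
              nrow(x$intensities), length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Read spectra from CSV
#'
#' First column must be named `ppm`; remaining columns are one sample each.
#' A descending ppm axis in the file is reversed losslessly on read.
#'
#' @param path Path to a CSV file.
#' @return A [spectra_matrix()].
#' @export
read_spectra_csv <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (tolower(colnames(raw)[1L]) != "ppm")
    abort("first column must be named 'ppm', got '%s'", colnames(raw)[1L])
  ppm <- raw[[1L]]
  mat <- t(as.matrix(raw[, -1L, drop = FALSE]))
  if (all(diff(ppm) < 0)) {          # stored descending on disk
    ppm <- rev(ppm)
    mat <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  }
  if (any(diff(ppm) <= 0)) abort("ppm not strictly monotone")
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    abort("missing intensity for sample '%s' at ppm %.4f",
          rownames(mat)[bad[1L]], ppm[bad[2L]])
  }
  spectra_matrix(ppm, mat)
}

#' Write spectra as CSV (descending ppm, NMR display convention)
#'
#' @param spec A [spectra_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spec, path) {
  idx <- rev(seq_along(spec$ppm))
  df <- data.frame(ppm = spec$ppm[idx],
                   t(spec$intensities[, idx, drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
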