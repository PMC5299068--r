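#' Validate an OTU count matrix
#'
#' An OTU table is a plain numeric matrix of non-negative integer counts with
#' taxa as rows and samples as columns; row names are taxon identifiers
#' (semicolon-delimited lineages allowed) and column names are sample
#' identifiers. Both must be unique, and the table needs at least one taxon
#' and two samples.
#'
#' @param counts Numeric matrix, taxa x samples.
#' @return The validated matrix, invisibly classed as `"otu_table"`.
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("OTU table must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("OTU table needs taxon row names and sample column names")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    abort("OTU table needs at least 1 taxon and 2 samples")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort("invalid count at (%s, %s): must be a non-negative integer",
          rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]])
  if (anyDuplicated(rownames(counts)))
    abort("duplicate taxon id: %s",
          rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    abort("duplicate sample id: %s",
          colnames(counts)[duplicated(colnames(counts))][1L])
  storage.mode(counts) <- "double"
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' Read an OTU count table from TSV
#'
#' Expects a header row of sample ids, a first column of taxon ids, and
#' integer cells. Column order is preserved.
#'
#' @param path Path to a tab-separated file.
#' @return An [otu_table()] matrix.
#' @export
read_otu_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L) abort("OTU table needs a taxon column and >= 2 samples")
  taxa <- raw[[1L]]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(taxa, colnames(m))))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    abort("invalid count at (%s, %s): %s", taxa[bad[1L, 1L]],
          colnames(num)[bad[1L, 2L]], m[bad[1L, , drop = FALSE]])
  otu_table(num)
}

#' Write an OTU count table as TSV
#'
#' Inverse of [read_otu_table()]: integer cells round-trip bit-identically.
#'
#' @param counts OTU matrix (taxa x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(counts, path) {
  df <- data.frame(taxon_id = rownames(counts),
                   format(counts, scientific = FALSE, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
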