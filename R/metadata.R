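GROUP_LEVELS <- c("control", "mild", "strong")
TIMEPOINT_LEVELS <- c("T1", "T2", "T3")

#' Validate a sample metadata table
#'
#' Metadata carries the study design: one row per sample with the subject
#' (mouse) it came from, its treatment group and its collection time point.
#' Groups follow the study contrast: an untreated control, a mild
#' perturbation (ciprofloxacin-like) and a strong one
#' (vancomycin-imipenem-like); time points are baseline (T1), end of
#' treatment (T2) and recovery (T3).
#'
#' @param df Data frame with columns `sample_id`, `subject_id`, `group`,
#'   `timepoint`.
#' @return The validated data frame with `group`/`timepoint` as factors.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "subject_id", "group", "timepoint")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    abort("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    abort("duplicate sample_id: %s", df$sample_id[duplicated(df$sample_id)][1L])
  bad_g <- setdiff(unique(as.character(df$group)), GROUP_LEVELS)
  if (length(bad_g) > 0L)
    abort("unknown group '%s' (allowed: %s)", bad_g[1L],
          paste(GROUP_LEVELS, collapse = ", "))
  bad_t <- setdiff(unique(as.character(df$timepoint)), TIMEPOINT_LEVELS)
  if (length(bad_t) > 0L)
    abort("unknown timepoint '%s' (allowed: %s)", bad_t[1L],
          paste(TIMEPOINT_LEVELS, collapse = ", "))
  key <- paste(df$subject_id, df$timepoint)
  if (anyDuplicated(key))
    abort("duplicate (subject, timepoint) pair: %s", key[duplicated(key)][1L])
  df$group <- factor(as.character(df$group), levels = GROUP_LEVELS)
  df$timepoint <- factor(as.character(df$timepoint), levels = TIMEPOINT_LEVELS)
  df[need]
}

#' Read sample metadata from TSV
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `subject_id`, `group`, `timepoint`.
#' @return A validated metadata data frame.
#' @export
read_metadata <- function(path) {
  sample_metadata(utils::read.delim(path, header = TRUE,
                                    colClasses = "character"))
}

#' Write sample metadata as TSV
#' @param meta Metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# align metadata rows to a set of sample ids (order preserved), erroring on
# samples without metadata; extra metadata rows are tolerated (the study
# dropped a few mice per assay, so unbalanced subsets must work)
match_metadata <- function(meta, sample_ids) {
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx))
    abort("sample(s) missing from metadata: %s",
          paste(sample_ids[is.na(idx)], collapse = ", "))
  meta[idx, , drop = FALSE]
}
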