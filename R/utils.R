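#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed for a pipeline stage
#'
#' A single root seed drives the whole pipeline; each stage draws its own
#' stream from a seed derived deterministically from the root seed and the
#' stage name, so adding or re-running one stage never perturbs another.
#'
#' @param seed Integer root seed.
#' @param stage Character stage name (e.g. `"otu"`, `"spectra"`).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps everything in 32-bit integer range
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer((abs(seed) %% m + h) %% m + 1)
}

# stop() with a consistent prefix; keeps error text grep-able in tests
abort <- function(...) stop(sprintf(...), call. = FALSE)

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) &&
    all(x >= 0) && all(x == round(x))
}

# column-wise relative abundance
rel_abundance <- function(counts) {
  cs <- colSums(counts)
  if (any(cs <= 0)) abort("all-zero sample column(s): %s",
                          paste(colnames(counts)[cs <= 0], collapse = ", "))
  sweep(counts, 2, cs, "/")
}

# trapezoidal integral on an arbitrary (ascending) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
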