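#' Pipeline run configuration
#'
#' Collects the tunable parameters of every stage with defaults matching the
#' published analysis protocol: rarefaction to the minimum library size,
#' 9,999 PERMANOVA permutations, 0.5--8.5 ppm spectral window with water and
#' reference-peak exclusion, 0.005-ppm minimum bucket width, double
#' cross-validation with a 75/25 stratified split repeated 2,000 times with
#' at most 8 components, LDA effect cutoff 3.0, 2-fold/FDR-0.05 volcano
#' gates, 70% SIMPER cumulative cutoff and |r| > 0.75 / q < 0.01 correlation
#' gates.
#'
#' @param seed Integer root seed for all stochastic stages.
#' @param ... Named overrides of the defaults (unknown names are rejected).
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    rarefy_depth = NA_integer_,        # NA = minimum column sum
    n_permutations = 9999L,
    lefse_alpha = 0.05,
    lefse_cutoff = 3.0,
    exclude_regions = list(c(-Inf, 0.5), c(8.5, Inf), c(4.7, 4.9),
                           c(-0.05, 0.05)),
    align_segment_ppm = 0.1,
    align_max_shift_ppm = 0.02,
    bucket_min_width_ppm = 0.005,
    cv_repeats = 2000L,
    cv_test_fraction = 0.25,
    cv_max_components = 8L,
    volcano_fc_threshold = 2.0,
    volcano_q_threshold = 0.05,
    simper_cum_cutoff = 0.70,
    metabolite_p_cutoff = 0.05,
    corr_r_threshold = 0.75,
    corr_q_threshold = 0.01
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path Path to a YAML file of config keys.
#' @return A [run_config()] (unknown keys rejected).
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$exclude_regions))
    vals$exclude_regions <- lapply(vals$exclude_regions, as.numeric)
  do.call(run_config, c(list(seed = vals$seed %||% 1L),
                        vals[setdiff(names(vals), "seed")]))
}

#' Write a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
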