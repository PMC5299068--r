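#' Simulation design for a three-arm antibiotic challenge study
#'
#' Encodes the study layout the generator emulates: three groups of mice
#' (untreated control, a mild ciprofloxacin-like arm, a strong
#' vancomycin-imipenem-like arm), eight subjects per group, sampled at
#' baseline (T1), end of treatment (T2) and recovery (T3). Planted effects
#' are multiplicative on taxon abundance at T2; at T3 log-abundances are
#' interpolated back toward baseline by a per-group recovery fraction (the
#' strong arm recovers more slowly). Metabolite effects and sparse
#' taxon-to-metabolite couplings provide ground truth for the metabolome and
#' integration stages.
#'
#' Default effect sizes: the strong arm depletes 40 taxa 100-fold and blooms
#' 10 taxa 20-fold (broad anaerobe loss with a Proteobacteria-like bloom);
#' the mild arm depletes 10 of the same taxa 5-fold. Defaults reproduce the
#' qualitative ordering strong >> mild, not any published effect size.
#'
#' @param n_subjects_per_group Mice per arm (default 8).
#' @param n_taxa,n_metabolites Feature counts (defaults 150 and 30).
#' @param library_size_log_mean,library_size_log_sd Log-normal sequencing
#'   depth parameters (defaults `log(2e4)` and 0.3).
#' @param taxon_log_sd Spread of taxon mean log-abundances (rank-abundance
#'   skew, default 1.5).
#' @param subject_log_sd Subject-specific baseline deviation per taxon
#'   (random intercept, default 0.4).
#' @param sample_log_sd Residual per-sample log-abundance noise (default 0.2).
#' @param effects Per-group list of taxon effects, each a list of
#'   `list(taxa = indices, factor = multiplier)` entries.
#' @param metabolite_effects Per-group named numeric vector of multiplicative
#'   concentration factors, names = metabolite indices.
#' @param recovery_fraction Named per-group fraction of the planted log
#'   effect removed by T3 (1 = full recovery).
#' @param coupling Data frame with columns `taxon`, `metabolite`, `weight`:
#'   log-concentration gains `weight * log(relative abundance)` of the taxon.
#' @param metabolite_log_sd Baseline spread of metabolite log concentrations.
#' @param metabolite_noise_sd Per-sample log-concentration noise (default
#'   0.4, the scale of biological within-group variability in fecal NMR).
#' @param dilution_log_sd Per-sample dilution spread on the log scale
#'   (default 0.3; exercises PQN).
#' @param shift_jitter_max_ppm Maximum whole-spectrum chemical-shift jitter
#'   (default 0.01 ppm; exercises alignment).
#' @param noise_sd_rel Additive spectral noise, relative to the median peak
#'   height (default 0.02).
#' @return A list of class `"simulation_design"`.
#' @export
simulation_design <- function(n_subjects_per_group = 8L,
                              n_taxa = 150L,
                              n_metabolites = 30L,
                              library_size_log_mean = log(2e4),
                              library_size_log_sd = 0.3,
                              taxon_log_sd = 1.5,
                              subject_log_sd = 0.4,
                              sample_log_sd = 0.2,
                              effects = NULL,
                              metabolite_effects = NULL,
                              recovery_fraction = c(control = 1, mild = 0.8,
                                                    strong = 0.5),
                              coupling = NULL,
                              metabolite_log_sd = 0.5,
                              metabolite_noise_sd = 0.4,
                              dilution_log_sd = 0.3,
                              shift_jitter_max_ppm = 0.01,
                              noise_sd_rel = 0.02) {
  if (is.null(effects)) {
    effects <- list(
      control = list(),
      mild = list(list(taxa = 1:10, factor = 0.2)),
      strong = list(list(taxa = 1:40, factor = 0.01),
                    list(taxa = 41:50, factor = 20))
    )
  }
  if (is.null(metabolite_effects)) {
    metabolite_effects <- list(
      control = numeric(0),
      mild = stats::setNames(c(rep(1.5, 3), rep(1 / 1.5, 3)), 1:6),
      strong = stats::setNames(c(rep(4, 7), rep(0.25, 7)), 1:14)
    )
  }
  if (is.null(coupling)) {
    coupling <- data.frame(
      taxon = c(11L, 12L, 41L, 42L, 13L, 14L),
      metabolite = c(1L, 2L, 3L, 4L, 8L, 9L),
      weight = c(1, 1, 1, 1, -1, -1)
    )
  }
  for (g in names(effects)) for (e in effects[[g]]) {
    if (any(e$factor <= 0)) abort("effect factors must be > 0")
    if (max(e$taxa) > n_taxa)
      abort("effect taxa exceed n_taxa = %d", n_taxa)
  }
  if (any(recovery_fraction < 0 | recovery_fraction > 1))
    abort("recovery_fraction must lie in [0, 1]")
  if (nrow(coupling) > 0L &&
      (max(coupling$taxon) > n_taxa || max(coupling$metabolite) > n_metabolites))
    abort("coupling indices exceed simulated feature counts")
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 groups = GROUP_LEVELS, timepoints = TIMEPOINT_LEVELS,
                 n_taxa = as.integer(n_taxa),
                 n_metabolites = as.integer(n_metabolites),
                 library_size_log_mean = library_size_log_mean,
                 library_size_log_sd = library_size_log_sd,
                 taxon_log_sd = taxon_log_sd, subject_log_sd = subject_log_sd,
                 sample_log_sd = sample_log_sd, effects = effects,
                 metabolite_effects = metabolite_effects,
                 recovery_fraction = recovery_fraction, coupling = coupling,
                 metabolite_log_sd = metabolite_log_sd,
                 metabolite_noise_sd = metabolite_noise_sd,
                 dilution_log_sd = dilution_log_sd,
                 shift_jitter_max_ppm = shift_jitter_max_ppm,
                 noise_sd_rel = noise_sd_rel),
            class = "simulation_design")
}

#' Null variant of a design (all planted effects removed)
#'
#' Groups become exchangeable: useful for calibration tests.
#' @param design A [simulation_design()].
#' @return The design with empty effect, metabolite-effect and coupling sets.
#' @export
null_design <- function(design = simulation_design()) {
  design$effects <- list(control = list(), mild = list(), strong = list())
  design$metabolite_effects <- list(control = numeric(0), mild = numeric(0),
                                    strong = numeric(0))
  design$coupling <- design$coupling[0, , drop = FALSE]
  design
}

# planted log-effect per taxon for one group at one timepoint
taxon_log_effect <- function(design, group, timepoint) {
  eff <- numeric(design$n_taxa)
  for (e in design$effects[[group]]) eff[e$taxa] <- log(e$factor)
  if (timepoint == "T1") eff[] <- 0
  if (timepoint == "T3") eff <- eff * (1 - design$recovery_fraction[[group]])
  eff
}

#' Simulate an OTU study with known ground truth
#'
#' Draws subject-specific baseline compositions (random intercepts on the
#' log scale), applies group effects at T2, interpolates toward baseline at
#' T3 by the group's recovery fraction, and samples counts multinomially per
#' sample conditional on a log-normal library size, so column sums equal the
#' drawn library sizes exactly and the data are explicitly compositional.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed.
#' @return List with `otu` (taxa x samples count matrix), `metadata`, and
#'   `truth` (planted effects, per-group affected taxa, couplings, library
#'   sizes, and the latent log-abundance matrix).
#' @export
simulate_otu_study <- function(design = simulation_design(), seed = 1L) {
  set.seed(derive_seed(seed, "otu"))
  ns <- design$n_subjects_per_group
  taxa <- sprintf("taxon_%03d", seq_len(design$n_taxa))
  subjects <- data.frame(
    subject_id = sprintf("%s_m%02d", rep(design$groups, each = ns),
                         seq_len(ns)),
    group = rep(design$groups, each = ns)
  )
  meta <- do.call(rbind, lapply(design$timepoints, function(tp) {
    data.frame(sample_id = paste0(subjects$subject_id, "_", tp),
               subject_id = subjects$subject_id, group = subjects$group,
               timepoint = tp)
  }))
  meta <- meta[order(meta$subject_id, meta$timepoint), ]
  rownames(meta) <- NULL
  meta <- sample_metadata(meta)

  taxon_mu <- stats::rnorm(design$n_taxa, 0, design$taxon_log_sd)
  base <- sapply(seq_len(nrow(subjects)), function(i)
    taxon_mu + stats::rnorm(design$n_taxa, 0, design$subject_log_sd))
  colnames(base) <- subjects$subject_id

  n <- nrow(meta)
  loglam <- matrix(0, design$n_taxa, n, dimnames = list(taxa, meta$sample_id))
  for (i in seq_len(n)) {
    loglam[, i] <- base[, meta$subject_id[i]] +
      taxon_log_effect(design, as.character(meta$group[i]),
                       as.character(meta$timepoint[i])) +
      stats::rnorm(design$n_taxa, 0, design$sample_log_sd)
  }
  lib <- pmax(100L, round(stats::rlnorm(n, design$library_size_log_mean,
                                        design$library_size_log_sd)))
  counts <- matrix(0, design$n_taxa, n, dimnames = dimnames(loglam))
  for (i in seq_len(n)) {
    p <- exp(loglam[, i] - max(loglam[, i]))
    counts[, i] <- stats::rmultinom(1L, lib[i], p / sum(p))
  }

  affected <- lapply(design$effects, function(es) {
    do.call(rbind, c(list(data.frame(taxon = integer(0), factor = numeric(0))),
                     lapply(es, function(e)
                       data.frame(taxon = e$taxa, factor = e$factor))))
  })
  truth <- list(affected_taxa = affected,
                metabolite_effects = design$metabolite_effects,
                coupling = design$coupling,
                library_sizes = stats::setNames(lib, meta$sample_id),
                log_abundance = loglam)
  list(otu = otu_table(counts), metadata = meta, truth = truth)
}
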