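# unit-area Lorentzian line shape, half-width-at-half-maximum gamma (ppm)
lorentzian <- function(ppm, center, gamma) {
  (gamma / pi) / ((ppm - center)^2 + gamma^2)
}

#' Simulate 1H-NMR spectra coupled to a simulated OTU study
#'
#' Each metabolite is assigned 1--3 Lorentzian peaks at fixed positions
#' inside the analytical window (0.5--8.5 ppm, avoiding the water region).
#' Per-sample log-concentration is baseline + planted group effect +
#' coupling weight times the log relative abundance of linked taxa + noise;
#' the spectrum is the concentration-weighted peak sum, multiplied by a
#' log-normal per-sample dilution factor, shifted as a whole by a per-sample
#' chemical-shift jitter (an integer number of grid points), with optional
#' additive noise. The grid is 0.2--9.5 ppm in 0.001-ppm steps.
#'
#' @param design A [simulation_design()].
#' @param otu Count matrix from [simulate_otu_study()] (taxa x samples).
#' @param metadata Matching metadata (one row per OTU sample).
#' @param seed Integer seed.
#' @param dilution_factors Optional numeric vector (one per sample)
#'   overriding the random dilution draw; used to plant known dilutions.
#' @param log_abundance Optional latent log-abundance matrix (taxa x
#'   samples, as returned in the OTU simulation's ground truth). When
#'   supplied, metabolite couplings act on the latent composition --- the
#'   true bacterial load a metabolite responds to --- rather than on
#'   observed counts, whose sampling zeros would otherwise inject
#'   pseudocount artefacts into the planted concentrations.
#' @return List with `spectra` (a [spectra_matrix()]) and `truth`
#'   (concentration matrix, peak table, per-sample dilution factors and
#'   shift offsets in ppm).
#' @export
simulate_spectra <- function(design, otu, metadata, seed = 1L,
                             dilution_factors = NULL, log_abundance = NULL) {
  meta <- match_metadata(metadata, colnames(otu))
  step <- 0.001
  ppm <- seq(0.2, 9.5, by = step)
  nm <- design$n_metabolites
  metab_ids <- sprintf("metab_%02d", seq_len(nm))

  # peak layout is design-level: fixed across samples, seeded separately so
  # the same metabolite map is reusable across count-table draws
  set.seed(derive_seed(seed, "peaks"))
  allowed <- c(0.6, 4.55, 5.05, 8.4)   # stay clear of the excluded windows
  peaks <- do.call(rbind, lapply(seq_len(nm), function(m) {
    k <- sample(1:3, 1L)
    lo_hi <- matrix(allowed, 2)
    seg <- sample(1:2, k, replace = TRUE, prob = c(0.55, 0.45))
    center <- round(stats::runif(k, lo_hi[1L, seg], lo_hi[2L, seg]) / step) * step
    data.frame(metabolite = metab_ids[m], center = center,
               gamma = stats::runif(k, 0.002, 0.006),
               height = stats::runif(k, 0.5, 1))
  }))
  if (any(peaks$center < min(ppm)) || any(peaks$center > max(ppm)))
    abort("peak ppm outside the simulated grid")

  # unit spectra: one row per metabolite at concentration 1
  unit <- matrix(0, nm, length(ppm), dimnames = list(metab_ids, NULL))
  for (i in seq_len(nrow(peaks))) {
    m <- peaks$metabolite[i]
    unit[m, ] <- unit[m, ] +
      peaks$height[i] * lorentzian(ppm, peaks$center[i], peaks$gamma[i])
  }

  set.seed(derive_seed(seed, "spectra"))
  base_log <- stats::rnorm(nm, 0, design$metabolite_log_sd)
  n <- ncol(otu)
  log_rel <- if (!is.null(log_abundance)) {
    if (!all(colnames(otu) %in% colnames(log_abundance)))
      abort("log_abundance must cover every OTU sample")
    la <- log_abundance[, colnames(otu), drop = FALSE]
    sweep(la, 2, log(colSums(exp(la))))
  } else {
    log(rel_abundance(unclass(otu)) + 1e-6)
  }
  # couplings act on deviations from the cohort-mean log abundance, so a
  # coupled metabolite's baseline level stays set by base_log regardless of
  # how rare its driver taxon is
  log_rel <- sweep(log_rel, 1, rowMeans(log_rel))
  logc <- matrix(0, n, nm, dimnames = list(colnames(otu), metab_ids))
  for (i in seq_len(n)) {
    g <- as.character(meta$group[i]); tp <- as.character(meta$timepoint[i])
    eff <- numeric(nm)
    me <- design$metabolite_effects[[g]]
    if (length(me) > 0L) {
      scl <- switch(tp, T1 = 0, T2 = 1,
                    T3 = 1 - design$recovery_fraction[[g]])
      eff[as.integer(names(me))] <- scl * log(me)
    }
    cpl <- numeric(nm)
    if (nrow(design$coupling) > 0L) {
      lra <- log_rel[design$coupling$taxon, i]
      for (j in seq_len(nrow(design$coupling)))
        cpl[design$coupling$metabolite[j]] <-
          cpl[design$coupling$metabolite[j]] + design$coupling$weight[j] * lra[j]
    }
    logc[i, ] <- base_log + eff + cpl +
      stats::rnorm(nm, 0, design$metabolite_noise_sd)
  }
  conc <- exp(logc)

  dilution <- if (is.null(dilution_factors))
    exp(stats::rnorm(n, 0, design$dilution_log_sd))
  else {
    if (length(dilution_factors) != n)
      abort("dilution_factors must have one entry per sample")
    as.numeric(dilution_factors)
  }
  max_pts <- round(design$shift_jitter_max_ppm / step)
  shifts <- if (max_pts > 0) sample(-max_pts:max_pts, n, replace = TRUE)
            else integer(n)

  intens <- (conc * dilution) %*% unit
  # whole-spectrum shift by an integer number of grid points, edge-padded
  for (i in seq_len(n)) {
    s <- shifts[i]
    if (s != 0) {
      v <- intens[i, ]
      if (s > 0) intens[i, ] <- c(rep(v[1L], s), v[seq_len(length(v) - s)])
      else intens[i, ] <- c(v[(1 - s):length(v)], rep(v[length(v)], -s))
    }
  }
  if (design$noise_sd_rel > 0) {
    med_h <- stats::median(peaks$height / (pi * peaks$gamma))
    intens <- intens + matrix(stats::rnorm(length(intens), 0,
                                           design$noise_sd_rel * med_h),
                              nrow = n)
    intens[intens < 0] <- 0
  }
  rownames(intens) <- colnames(otu)

  truth <- list(concentrations = conc, peaks = peaks,
                dilution = stats::setNames(dilution, colnames(otu)),
                shift_ppm = stats::setNames(shifts * step, colnames(otu)))
  list(spectra = spectra_matrix(ppm, intens), truth = truth)
}
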