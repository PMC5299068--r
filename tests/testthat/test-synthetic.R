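test_that("count matrix columns sum exactly to the drawn library sizes", {
  sim <- simulate_otu_study(small_design(), seed = 5)
  expect_identical(unname(colSums(sim$otu)),
                   as.numeric(sim$truth$library_sizes))
  expect_equal(dim(sim$otu), c(60L, 36L))
})

test_that("same seed reproduces the simulation exactly; seeds differ otherwise", {
  a <- simulate_otu_study(small_design(), seed = 11)
  b <- simulate_otu_study(small_design(), seed = 11)
  c <- simulate_otu_study(small_design(), seed = 12)
  expect_identical(unclass(a$otu)[, ], unclass(b$otu)[, ])
  expect_false(identical(unclass(a$otu)[, ], unclass(c$otu)[, ]))
})

test_that("null design makes groups exchangeable under PERMANOVA", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_otu_study(null_design(small_design()), seed = 100 + s)
    t2 <- sim$metadata$timepoint == "T2"
    d <- bray_curtis_sqrt(sim$otu[, t2])
    res <- permanova(d, droplevels(sim$metadata$group[t2]),
                     n_permutations = 99, seed = s)
    if (res$p_perm > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_seeds)
})

test_that("strong perturbation separates further from control than mild", {
  wins <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_otu_study(small_design(), seed = 200 + s)
    t2 <- which(sim$metadata$timepoint == "T2")
    d <- bray_curtis_sqrt(sim$otu[, t2])
    g <- sim$metadata$group[t2]
    d_strong <- mean(d[g == "control", g == "strong"])
    d_mild <- mean(d[g == "control", g == "mild"])
    if (d_strong > d_mild) wins <- wins + 1L
  }
  expect_gte(wins, 0.95 * n_seeds)
})

test_that("doubling the bloom factor never decreases group separation", {
  for (s in 1:10) {
    sep <- sapply(c(20, 40), function(f) {
      des <- small_design(effects = list(
        control = list(), mild = list(),
        strong = list(list(taxa = 1:20, factor = 0.05),
                      list(taxa = 41:45, factor = f))))
      sim <- simulate_otu_study(des, seed = 300 + s)
      t2 <- which(sim$metadata$timepoint == "T2")
      d <- bray_curtis_sqrt(sim$otu[, t2])
      g <- sim$metadata$group[t2]
      mean(d[g == "control", g == "strong"])
    })
    expect_gte(sep[2], sep[1])
  }
})

test_that("degenerate spectra generator yields identical samples", {
  des <- small_design(dilution_log_sd = 0, shift_jitter_max_ppm = 0,
                      noise_sd_rel = 0, metabolite_noise_sd = 0,
                      sample_log_sd = 0, subject_log_sd = 0,
                      effects = NULL, metabolite_effects = list(
                        control = numeric(0), mild = numeric(0),
                        strong = numeric(0)),
                      coupling = data.frame(taxon = integer(0),
                                            metabolite = integer(0),
                                            weight = numeric(0)))
  des$effects <- list(control = list(), mild = list(), strong = list())
  sim <- simulate_otu_study(des, seed = 4)
  # identical latent composition for every sample -> identical spectra
  la <- sim$truth$log_abundance
  la[] <- la[, 1]
  sp <- simulate_spectra(des, sim$otu, sim$metadata, seed = 4,
                         log_abundance = la)
  rng <- apply(sp$spectra$intensities, 2, function(v) diff(range(v)))
  expect_lt(max(rng), 1e-9)
})

test_that("spectra are linear in planted dilution factors", {
  des <- small_design(noise_sd_rel = 0, shift_jitter_max_ppm = 0,
                      metabolite_noise_sd = 0)
  des$effects <- list(control = list(), mild = list(), strong = list())
  des$metabolite_effects <- list(control = numeric(0), mild = numeric(0),
                                 strong = numeric(0))
  sim <- simulate_otu_study(des, seed = 6)
  la <- sim$truth$log_abundance
  la[] <- la[, 1]                       # identical composition everywhere
  dil <- rep(1, ncol(sim$otu))
  dil[1:3] <- c(1, 2, 4)
  sp <- simulate_spectra(des, sim$otu, sim$metadata, seed = 6,
                         log_abundance = la, dilution_factors = dil)
  ints <- sapply(1:3, function(i)
    dysbiome:::trapz(sp$spectra$ppm, sp$spectra$intensities[i, ]))
  expect_lt(max(abs(ints / ints[1] - c(1, 2, 4))), 1e-9)
})

test_that("planted couplings drive strong taxon-metabolite correlations", {
  rs <- sapply(1:10, function(s) {
    des <- simulation_design()
    sim <- simulate_otu_study(des, seed = 400 + s)
    sp <- simulate_spectra(des, sim$otu, sim$metadata, seed = 400 + s,
                           log_abundance = sim$truth$log_abundance)
    keep <- sim$metadata$group %in% c("control", "strong") &
      sim$metadata$timepoint == "T2"
    la <- sim$truth$log_abundance[, keep]
    lrel <- sweep(la, 2, log(colSums(exp(la))))
    cpl <- des$coupling[1L, ]
    cor(lrel[cpl$taxon, ],
        log(sp$truth$concentrations[keep, cpl$metabolite]),
        method = "spearman")
  })
  expect_gt(median(rs), 0.8)
})

test_that("fixture sets are complete and reproducible on disk", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  des <- small_design()
  man_a <- write_fixture_set(dir_a, des, seed = 9, overwrite = TRUE)
  man_b <- write_fixture_set(dir_b, des, seed = 9, overwrite = TRUE)
  expect_setequal(man_a$file, c("otu.tsv", "metadata.tsv", "spectra.csv",
                                "ground_truth.json", "config.yaml"))
  expect_identical(man_a$md5, man_b$md5)
  otu <- read_otu_table(file.path(dir_a, "otu.tsv"))
  expect_equal(dim(otu), c(60L, 36L))
  expect_error(write_fixture_set(dir_a, des, seed = 9), "not empty")
})
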