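test_that("default exclusions keep only the analytical window", {
  spec <- peak_spectra(2, ppm = seq(0.2, 9.5, by = 0.01))
  out <- exclude_regions(spec)
  expect_true(all(out$ppm >= 0.5 & out$ppm <= 8.5))
  expect_false(any(out$ppm > 4.7 & out$ppm < 4.9))
  same <- exclude_regions(spec, regions = list())
  expect_equal(same$intensities, spec$intensities)
  expect_error(exclude_regions(spec, regions = list(c(-Inf, Inf))),
               "whole axis")
})

test_that("alignment recovers a constructed shift and reports saturation", {
  ppm <- seq(1, 2, by = 0.001)
  base <- (0.004 / pi) / ((ppm - 1.5)^2 + 0.004^2)
  shifted <- c(rep(base[1], 7), base[seq_len(length(base) - 7)])  # +7 points
  spec <- spectra_matrix(ppm, rbind(base, base, base, shifted))
  al <- align_spectra(spec, segment_width_ppm = 1.001, max_shift_ppm = 0.01)
  sh <- attr(al, "shifts")
  expect_equal(unname(sh[sh[, "sample"] == 4, "offset"]), -7)
  expect_gt(cor(al$intensities[4, ], base), 0.999)
  # shift beyond max_shift saturates at the bound
  shifted12 <- c(rep(base[1], 12), base[seq_len(length(base) - 12)])
  spec2 <- spectra_matrix(ppm, rbind(base, base, base, shifted12))
  al2 <- align_spectra(spec2, segment_width_ppm = 1.001,
                       max_shift_ppm = 0.01)
  sh2 <- attr(al2, "shifts")
  expect_equal(unname(sh2[sh2[, "sample"] == 4, "offset"]), -10)
  expect_error(align_spectra(spec, segment_width_ppm = 0.001,
                             max_shift_ppm = 0.0005), "3 points")
})

test_that("identical spectra are never shifted", {
  spec <- peak_spectra(4, center = 2, ppm = seq(1, 3, by = 0.001))
  al <- align_spectra(spec, segment_width_ppm = 0.2, max_shift_ppm = 0.02)
  expect_true(all(attr(al, "shifts")[, "offset"] == 0))
  expect_equal(al$intensities, spec$intensities)
})

test_that("bucketing keeps uniform boundaries on a flat spectrum", {
  ppm <- seq(1, 1.1, by = 0.001)
  spec <- spectra_matrix(ppm, rbind(rep(1, length(ppm)), rep(2, length(ppm))))
  b <- adaptive_bucket(spec, min_width_ppm = 0.005)
  widths <- b$edges$ppm_hi - b$edges$ppm_lo
  expect_true(all(widths >= 0.005 - 1e-9))
  expect_lt(max(widths), 0.005 + 2 * 0.001 + 1e-9)
})

test_that("a bucket boundary lands in the valley between close peaks", {
  ppm <- seq(1, 1.2, by = 0.001)
  two <- (0.002 / pi) / ((ppm - 1.096)^2 + 0.002^2) +
         (0.002 / pi) / ((ppm - 1.108)^2 + 0.002^2)   # valley at 1.102
  spec <- spectra_matrix(ppm, rbind(two, two))
  b <- adaptive_bucket(spec, min_width_ppm = 0.005)
  bounds <- c(b$edges$ppm_lo, b$edges$ppm_hi)
  expect_true(any(abs(bounds - 1.102) < 1e-9))
})

test_that("bucket integrals conserve the spectrum integral", {
  set.seed(61)
  ppm <- seq(0.5, 8.5, by = 0.001)
  ints <- rbind(runif(length(ppm)), runif(length(ppm)) * 3)
  spec <- spectra_matrix(ppm, ints)
  b <- adaptive_bucket(spec, min_width_ppm = 0.005)
  for (i in 1:2) {
    expect_equal(sum(b$intensities[i, ]),
                 dysbiome:::trapz(ppm, ints[i, ]), tolerance = 1e-9)
  }
  expect_true(all(b$edges$ppm_hi - b$edges$ppm_lo >= 0.005 - 1e-9))
})

test_that("PQN removes scalar dilution exactly and is idempotent", {
  set.seed(62)
  base <- runif(40, 0.1, 1)
  x <- rbind(base, 2 * base, 4 * base, 0.5 * base)
  rownames(x) <- paste0("s", 1:4)
  b <- list(intensities = x)
  p1 <- pqn_normalize(b)
  expect_lt(max(abs(sweep(p1$intensities, 2,
                          p1$intensities[1, ]))), 1e-10)
  expect_equal(unname(p1$norm_factors / p1$norm_factors[1]),
               c(1, 2, 4, 0.5), tolerance = 1e-10)
  p2 <- pqn_normalize(p1)
  expect_equal(p2$intensities, p1$intensities, tolerance = 1e-10)
})

test_that("the median quotient ignores a minority of real changes", {
  set.seed(63)
  ref <- runif(50, 0.5, 1.5)
  changed <- ref
  changed[1:5] <- changed[1:5] * 2          # 10% of buckets truly doubled
  x <- rbind(ref, changed)
  rownames(x) <- c("ref", "changed")
  p <- pqn_normalize(list(intensities = x), reference = ref / sum(ref))
  # the overall normalization is driven by the unchanged 90% of buckets, so
  # the planted doublings survive and the rest stays put
  ratio <- p$intensities["changed", ] / p$intensities["ref", ]
  expect_equal(unname(ratio), c(rep(2, 5), rep(1, 45)), tolerance = 0.02)
  expect_error(pqn_normalize(list(intensities = rbind(ref, 0 * ref))),
               "zero total")
})

test_that("planted dilution factors are recovered through the full chain", {
  des <- small_design(noise_sd_rel = 0, shift_jitter_max_ppm = 0,
                      metabolite_noise_sd = 0)
  sim <- simulate_otu_study(des, seed = 64)
  la <- sim$truth$log_abundance
  la[] <- la[, 1]                # same composition: dilution is the only
  dil <- rep(1, ncol(sim$otu))   # sample-level difference among 1:3
  dil[1:3] <- c(1, 2, 4)
  sp <- simulate_spectra(des, sim$otu, sim$metadata, seed = 64,
                         log_abundance = la, dilution_factors = dil)
  b <- adaptive_bucket(exclude_regions(sp$spectra))
  p <- pqn_normalize(b)
  rec <- p$norm_factors[1:3] / p$norm_factors[1]
  expect_equal(unname(rec), c(1, 2, 4), tolerance = 0.02)
})

test_that("Pareto scaling matches its closed form and flags constants", {
  m <- cbind(a = c(1, 3), b = c(2, 2), c = c(0.5, -0.5))
  s <- pareto_scale(m)
  expect_equal(unname(s$data[, "a"]), c(-0.8409, 0.8409), tolerance = 1e-4)
  expect_equal(unname(s$data[, "b"]), c(0, 0))
  expect_true(s$constant["b"])
  expect_false(s$constant["a"])
  expect_equal(unname(colMeans(s$data)), c(0, 0, 0), tolerance = 1e-10)
  # already centered, unit sd: unchanged up to the sqrt(sd)=1 divisor
  z <- c(-0.5, 0.5) / sd(c(-0.5, 0.5))
  s2 <- pareto_scale(cbind(z = z))
  expect_equal(unname(s2$data[, 1]), z, tolerance = 1e-12)
})

test_that("preprocessing commutes with sample order", {
  des <- small_design()
  sim <- simulate_otu_study(des, seed = 65)
  sp <- simulate_spectra(des, sim$otu, sim$metadata, seed = 65,
                         log_abundance = sim$truth$log_abundance)
  sub <- spectra_matrix(sp$spectra$ppm, sp$spectra$intensities[1:6, ])
  perm <- c(3, 1, 6, 2, 5, 4)
  sub_p <- spectra_matrix(sp$spectra$ppm, sp$spectra$intensities[perm[1:6], ])
  run <- function(s) pqn_normalize(adaptive_bucket(exclude_regions(s)))
  a <- run(sub); b <- run(sub_p)
  expect_equal(a$intensities[rownames(b$intensities), ], b$intensities,
               tolerance = 1e-12)
})
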