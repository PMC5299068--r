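# dysbiome

Joint statistical analysis of fecal **microbiota** (16S OTU count tables)
and **¹H-NMR metabolome** profiles in antibiotic-perturbation studies.

Antibiotics reshape the gut on two levels that do not move in lockstep:
community composition (which taxa are there) and metabolic output (what
the community produces). Studies that profile both — typically a control
arm, a mildly disruptive agent and a strongly disruptive combination,
sampled before, at the end of, and after treatment — need a pipeline that
spans community ecology, NMR signal processing, supervised chemometrics
and cross-omic correlation. `dysbiome` provides that pipeline for
researchers analyzing such designs, along with a ground-truth synthetic
study generator so every stage is testable without external data.

## What it computes

**Community ecology** (taxa × samples count matrices):

* alpha diversity — richness *S*, Shannon *H* = −Σ *p*ᵢ ln *p*ᵢ, Simpson
  1 − *D* = 1 − Σ *p*ᵢ²; rarefaction to even depth
* Bray-Curtis dissimilarity on square-root relative abundances,
  *d*(u,v) = Σ|xᵤ−xᵥ| / Σ(xᵤ+xᵥ); NMDS ordination (Kruskal stress-1)
* one-way and pairwise **PERMANOVA** (pseudo-*F* from the partition of
  squared distances, permutation *p* = (1+b)/(1+m), pairwise
  *t* = √*F*), **PERMDISP** (distance to group centroid in
  principal-coordinate space with the negative-eigenvalue correction),
  **SIMPER** (exact per-taxon decomposition of between-group
  dissimilarity), and a deterministic two-class **LDA effect score**
  (log₁₀ scale, 3.0 cutoff) for discriminant taxa
* mean percent similarity 100(1 − d̄) between groups

**NMR preprocessing** (ppm × samples spectra): region exclusion
(0.5–8.5 ppm window, water, reference peak), segment-wise alignment to the
median spectrum, adaptive bucketing with a 0.005-ppm minimum width and
exact integral conservation, probabilistic quotient normalization (PQN),
Pareto scaling.

**Chemometrics**: NIPALS PLS-DA, an OPLS filter (orthogonal signal
removal), and a stratified 75/25 **double cross-validation** — inner
leave-one-out F1 chooses the component count (max 8), the final model is
an OPLS filter of (k−1) components plus a 2-component PLS-DA, and test-set
predictive ability

  Q² = 1 − Σ(y − ŷ)² / Σ(y − ȳ_train)²

is aggregated over repeated random splits (2,000 by default), with a
permuted-label reference distribution as the null benchmark, and
back-scaled loadings for interpretation on the original intensity scale.

**Integration**: volcano tables (log₂ fold change, Mann-Whitney *p*,
Benjamini-Hochberg *q*, 2-fold / *q* ≤ 0.05 gate), feature gating by
SIMPER cumulative contribution (70%) and volcano *q* (0.05), Spearman
correlation matrices with joint BH adjustment masked at |r| > 0.75 and
*q* < 0.01, and Ward-linkage leaf ordering for heatmap axes.

## Worked example

Simulate the default three-arm study (3 groups × 8 mice × 3 time points,
150 taxa, 30 metabolites), test composition shifts at the end of
treatment, and quantify the metabolome separation of the strongly
perturbed arm:

```r
library(dysbiome)

des <- simulation_design()
sim <- simulate_otu_study(des, seed = 1)
sp  <- simulate_spectra(des, sim$otu, sim$metadata, seed = 1,
                        log_abundance = sim$truth$log_abundance)

## microbiota: pairwise PERMANOVA at end of treatment (T2)
t2 <- sim$metadata$timepoint == "T2"
d  <- bray_curtis_sqrt(sim$otu[, t2])
pairwise_permanova(d, droplevels(sim$metadata$group[t2]),
                   n_permutations = 999, seed = 1)
#>   group_a group_b    t pseudo_f p_perm
#> 1 control    mild 1.44     2.08  0.002
#> 2 control  strong 7.02    49.21  0.001
#> 3    mild  strong 6.74    45.39  0.001

## metabolome: preprocess spectra and run double-CV OPLS-DA
pq <- pqn_normalize(adaptive_bucket(align_spectra(exclude_regions(
  sp$spectra))))
sel <- t2 & sim$metadata$group %in% c("control", "strong")
x <- pq$intensities[sim$metadata$sample_id[sel], ]
y <- ifelse(droplevels(sim$metadata$group[sel]) == "strong", 1, -1)
cv  <- double_cv(x, y, n_repeats = 100, seed = 1)
ref <- permuted_reference_q2(x, y, n_repeats = 100, seed = 1)
sprintf("Q2 mean %.3f (median %.3f); permuted-label reference mean %.3f",
        cv$q2_mean, cv$q2_median, ref$q2_mean)
#> "Q2 mean 0.769 (median 0.847); permuted-label reference mean -1.016"
```

The pairwise *t* statistics say both antibiotic arms shifted community
composition away from control, the strong arm far more (t = 7.02 vs 1.44).
The metabolome of the strong arm is highly predictable from class labels
under honest held-out validation (Q² ≈ 0.77 against a chance reference
around −1), mirroring how a broad-spectrum regimen remodels both the
community and its metabolic output.

A thin command-line wrapper covers the same stages
(`inst/cli/dysbiome simulate|ecology|nmr|oplsda|integrate ...`); all
outputs are byte-reproducible for a fixed `--seed`.

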