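---
title: "Methods: joint microbiota-metabolome analysis of antibiotic perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint microbiota-metabolome analysis of antibiotic perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbiome)
```

# Scope

`dysbiome` implements a complete statistical pipeline for studies that
profile the gut ecosystem on two levels at once: 16S rRNA OTU count tables
for community composition and 1D ^1^H-NMR spectra for the fecal metabolome.
The motivating design is an antibiotic-challenge experiment in mice — an
untreated control arm, a mild perturbation (a ciprofloxacin-like agent with
limited anti-anaerobe activity) and a strong one (a
vancomycin-imipenem-like combination that depletes most anaerobes) — with
eight subjects per arm sampled at baseline (T1), at the end of treatment
(T2) and after a recovery period (T3). Every stage is exercised end-to-end
on a synthetic study generator with known ground truth, so the package
needs no external data to validate itself.

# The synthetic study generator

The generator is first-class, tested code, not a fixture. Its defaults
define the study conditions used throughout the test suite and the
acceptance script.

**Community model.** Each taxon gets a mean log-abundance drawn with
spread 1.5 (a log-normal rank-abundance profile); each mouse adds a
taxon-specific random intercept (sd 0.4), reflecting the observation that
baseline microbiotas differ even between genetically identical animals,
plus per-sample noise (sd 0.2). Treatment effects are multiplicative on
abundance at T2: the strong arm depletes 40 taxa 100-fold and blooms 10
taxa 20-fold (broad anaerobe loss with a Proteobacteria-like bloom); the
mild arm depletes 10 of the same taxa 5-fold. At T3 the planted log-effect
is shrunk by a per-arm recovery fraction (0.8 mild, 0.5 strong), encoding
the slower recovery after the strong regimen. Counts are drawn
multinomially conditional on a log-normal library size (median 20,000
reads), so column sums equal the drawn depths exactly and the data are
explicitly compositional.

**Metabolome model.** Thirty metabolites each receive 1–3 Lorentzian peaks
at fixed positions inside the analytical window on a 0.2–9.5 ppm grid with
0.001-ppm steps. Per-sample log-concentration is a metabolite baseline
(spread 0.5) plus a planted arm effect (strong: 14 metabolites shifted
4-fold up or down; mild: 6 metabolites 1.5-fold), plus coupling terms, plus
within-group biological noise with sd 0.4 — the scale of replicate
variability we consider realistic for fecal extracts; anything much
tighter would make even the mild arm an effectively noise-free contrast.
Sparse taxon–metabolite couplings (six pairs, weights ±1) tie metabolite
log-concentrations to the *deviation of the latent log relative abundance
from its cohort mean* for taxa perturbed only in the strong arm. Two
modelling points matter here:

* couplings act on the latent composition rather than on observed counts,
  because sampling zeros of a 100-fold-depleted taxon would otherwise
  inject pseudocount artefacts of several log-units into the planted
  concentrations; and
* centering on the cohort mean keeps a coupled metabolite's baseline level
  set by its own baseline term — coupling to the absolute log-abundance of
  a rare taxon would scale the metabolite by `1/abundance` and let a
  single feature dominate the whole feature space.

Spectra are the concentration-weighted peak sums, multiplied by a
per-sample log-normal dilution factor (sd 0.3, exercising PQN), shifted as
a whole by up to ±0.01 ppm in integer grid steps (exercising alignment),
with additive noise at 2% of the median peak height.

**What the generator does not emulate.** Real multiplet structure and
J-coupling, peak-shape distortions, baseline drift, chemical-shift
dependence on pH, phylogenetic correlation between taxa, and any
host-physiology feedback. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under a
plausible data-generating process, not performance guarantees on real
spectra.

# Community-ecology statistics

Alpha diversity reports richness S, Shannon H (nats) and Simpson 1−D from
per-sample relative abundances; rarefaction subsamples without replacement
to even depth (default: the minimum library). Beta diversity uses
Bray-Curtis dissimilarities of square-root-transformed relative
abundances; percent similarity is `100 (1 − d)`. NMDS minimizes Kruskal
stress-1 (vegan's `monoMDS`, global model) with the metric
principal-coordinate solution as first start and random restarts, returning
the best solution rotated to principal axes.

**PERMANOVA** partitions the total sum of squared distances into between-
and within-group components (one-way pseudo-F). For the one-way and
pairwise designs handled here, permuting raw labels coincides with
permutation of residuals under a reduced model without covariates, so the
simpler scheme is used. The p-value uses the `(1 + b)/(1 + m)` estimator
and is never zero; a requested permutation count is always used in full
(duplicate permutations are not discarded, so `m` is exact). Pairwise
comparisons report `t = sqrt(F)` and the square root of the estimated
component of variation `sqrt(max(0, (MS_b − MS_w)/n̄))` for parity with
standard community-ecology software output; the latter is reported only,
never used in decisions.

**PERMDISP** embeds the distance matrix by principal coordinates, keeps
positive- and negative-eigenvalue axes separately, and computes distances
to the group *centroid* (not spatial median) with the imaginary-axis
correction (squared real-part distance minus squared imaginary-part
distance, floored at zero). The F statistic on those distances is tested
by permuting their least-squares residuals. Calibration is verified by
simulation (null rejection within [0.02, 0.08] at α = 0.05).

**SIMPER** decomposes the mean between-group dissimilarity into additive
per-taxon terms; the decomposition identity (contributions sum exactly to
the mean between-group Bray-Curtis value) is enforced to 1e-10 in tests.
Note that compositional closure means a manipulation of one taxon always
leaks a little contribution into every other taxon, so a "single changed
taxon" never reaches exactly 100%.

**LDA effect scores** are a deterministic two-class variant of the LEfSe
idea: features in relative-abundance-per-million units are gated by a
two-sided Mann-Whitney test at α = 0.05, survivors enter a Fisher
discriminant with a diagonal ridge (1e-3 of the mean within-class
variance) for stability when features outnumber samples, and the effect
size per feature averages its univariate mean difference with its share of
the discriminant-axis separation; the score is `log10(1 + effect)` with
the conventional 3.0 cutoff. No bootstrap and no subclass logic: results
are reproducible without a seed, which is what makes the cutoff testable.
Wilcoxon/Mann-Whitney machinery is delegated to `stats::wilcox.test`
(exact for small untied samples, normal approximation with continuity
correction otherwise).

# NMR preprocessing

The chain is exclusion → alignment → bucketing → PQN → Pareto, in that
order, and is fully deterministic.

* **Exclusion** removes noise regions below 0.5 and above 8.5 ppm, the
  water peak and the TSP reference. The water and TSP windows default to
  (4.7, 4.9) and (−0.05, 0.05) ppm — the peaks are standard, their widths a
  package choice, both configurable.
* **Alignment** is a segment-wise, integer-point correction against the
  pointwise median spectrum. Cosine similarity (not a raw dot product)
  scores candidate shifts, because edge padding otherwise rewards spurious
  shifts on monotone segments; ties go to the smallest |offset|, then the
  more negative one. Only whole grid-point shifts are applied — no
  sub-point interpolation — which keeps the operation exactly invertible
  and testable.
* **Bucketing** starts from uniform boundaries at the minimum width
  (default 0.005 ppm) and relocates each interior boundary to the local
  minimum of the mean spectrum within half a bucket width, subject to all
  widths staying at or above the minimum; boundary relocation can only
  consume the slack the width constraint leaves. Bucket values are
  trapezoidal integrals, so each spectrum's total integral is conserved
  exactly. The resulting bucket count depends on the grid and exclusions,
  not on any fixed target.
* **PQN** first normalizes each sample to unit total integral, then
  divides by the median bucket-wise quotient against the median reference
  spectrum. Because integral normalization comes first, the median
  quotient is near 1 and the dilution information lives in the *product*
  of integral factor and quotient; that product is exposed as
  `norm_factors` and is the quantity proportional to the true dilution
  (recovered within 2% in tests). PQN is exactly idempotent.
* **Pareto scaling** centers columns and divides by the square root of the
  sample standard deviation (n − 1); constant columns are centered, left
  unscaled and flagged.

# Chemometrics: NIPALS OPLS-DA with double cross-validation

The discriminant engine codes classes ±1 and fits PLS1 components by
NIPALS: `w ∝ X'y`, `t = Xw`, `q = t'y/t't`, `p = X't/t't`, then deflation
of both blocks (with one response the inner loop is closed-form per
component). Prediction uses the coefficient form `B = W(P'W)^{-1}q`; the
tie `ŷ = 0` is assigned to class +1. The OPLS filter removes components
built from the part of the loading not collinear with the weight; its
scores are uncorrelated with the response by construction, and the filter
stops early (recording the actual count) when no orthogonal variation
remains.

Model selection and validation follow a double cross-validation: the outer
loop draws a stratified 75/25 train/test split (test counts proportional
per class, at least one test sample per class) and all centering/scaling
statistics come from the training rows only; the inner loop chooses the
component count in 1..8 by leave-one-out F1 (positive class = treatment,
ties to fewer components); the final model applies an OPLS filter with
(chosen − 1) components and fits a 2-component PLS-DA on the filtered
data, giving one predictive and one within-model orthogonal component.
Predictions use both components by default (a flag restricts to the
predictive one); the predictive component's sign is fixed so positive
back-scaled loadings mean elevated in the +1 class. Test-set predictive
ability is `Q² = 1 − PRESS/TSS` with the training-mean denominator — the
test-set-mean variant is unstable for 4-sample test sets. The procedure
repeats 2,000 times by default with fresh random splits; the same
procedure run after randomly permuting the labels provides the reference
Q² distribution. Both the mean and the median Q² across repeats are
reported; the mean is the headline aggregate. The Q² distribution under
small n is heavy-tailed to the left (an unlucky split with an overfitted
filter can yield a strongly negative repeat), which is why the median is
reported alongside.

Tests and the acceptance script scale the repeat count to 50–100: the
per-repeat distribution is identical (repeats are i.i.d. across splits),
only the Monte-Carlo error of the aggregate grows, which the test margins
absorb. The NIPALS core is cross-checked against an independent reference
implementation (mixOmics) to 1e-8.

# Integration: volcano gating and thresholded correlation

The volcano table computes per-feature log2 fold changes of group means
(against the control arm), Mann-Whitney p-values (the test is the package
default for consistency with the taxon-level testing; Welch's t is behind
a flag) and Benjamini-Hochberg q-values; the significance gate is a 2-fold
change with q ≤ 0.05. Features with a non-positive group mean have an
undefined fold change and are never flagged.

Feature gating into the correlation layer takes the minimal SIMPER prefix
reaching 70% cumulative contribution (taxa) and the features with volcano
q ≤ 0.05 (metabolites) — the q-value, not the raw p, since the gate is
described as FDR-adjusted. Spearman correlations (mid-rank ties) are
computed for every selected taxon × metabolite pair; p-values are exact by
full permutation enumeration for n ≤ 9 with untied data and use the
t-approximation otherwise; BH adjustment is applied jointly across the
whole grid (NA cells from constant vectors are excluded from the family);
the significance mask requires |r| > 0.75 and q < 0.01. Heatmap axes are
ordered by Ward clustering (`ward.D2`) on Euclidean distances, with
Bray-Curtis available for taxon-abundance heatmaps. Correlations are
computed on PQN-normalized, unscaled values: Spearman is invariant to the
per-sample scaling PQN applies and to any monotone transform, so Pareto
scaling would not change the ranks.

# Numerical and degenerate-input choices

* Distance matrices must be symmetric to 1e-12 with zero diagonal;
  all-identical data give pseudo-F = 0 and p = 1.
* Permutation p-values use `(1 + b)/(1 + m)`; observed-statistic
  comparisons use a 1e-12 slack so exact ties count as exceedances.
* The PLS rank bound is `min(n − 1, p)`; weight vectors below 1e-12 in
  norm stop component extraction.
* Constant features: Pareto leaves them unscaled and flags them; the
  correlation layer yields NA cells excluded from the BH family; LDA uses
  a diagonal ridge.
* A single root seed derives per-stage child seeds by hashing the stage
  name, so adding or re-running one stage never perturbs another, and all
  seeds stay below 2^31.

# Problem sizes used in validation

The default study (3 × 8 × 3 samples, 150 taxa, 30 metabolites, ~1,550
buckets) is used for the end-to-end checks; calibration checks use 500
null simulations with 99 permutations each; double-CV checks use 100
repeats on 16-sample two-class problems; alignment recovery uses 50
constructed shifts; the exact-decomposition and entropy-bound properties
run over 200 and 1,000 random draws. These sizes were chosen so the whole
validation suite completes in a few minutes while keeping Monte-Carlo
error well inside the asserted margins.

# Known limitations

* Only one-way and pairwise PERMANOVA designs are supported — no
  multi-factor or nested permutation schemes.
* The LDA effect score is a deterministic simplification; scores are
  comparable to bootstrap LEfSe in spirit, not numerically.
* The bucketing boundary rule is a documented local-minimum stand-in for
  "optimized bucketing"; with initial boundaries at exactly the minimum
  width, boundaries can drift only forward within the width constraint.
* Alignment uses integer-point shifts; sub-point misalignment smaller than
  one grid step is not corrected.
* Heavy left tails of the per-repeat Q² distribution are inherent to
  double CV at n = 16 and are reported, not suppressed.
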