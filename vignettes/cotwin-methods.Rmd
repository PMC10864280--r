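---
title: "Pyramid-layer co-twin analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyramid-layer co-twin analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotwin)
```

# The scientific problem

Cross-sectional case–control comparisons of the gut microbiome are
dominated by inter-individual variability: host genetics, early-life
environment, diet and medication all shape microbial composition, and any
of them can masquerade as a disease association. A co-twin control design
removes most of this variation by construction. Monozygotic (MZ) co-twins
share all germline variants and most early environment; dizygotic (DZ)
co-twins share on average half their segregating variants and the same
household. Comparing a disease-discordant twin against their own healthy
co-twin therefore cancels shared genetic and early-environmental
confounding, at the cost of a small sample: discordant pairs are rare.

`cotwin` implements a layered ("pyramid") analysis over a twin cohort
with binary disease status (`md`), a genus-level microbial count table, a
metabolite panel and a predicted-pathway table:

* **Layer a** — paired tests within MZ-discordant pairs (strongest
  control, smallest n).
* **Layer b** — paired tests within DZ-discordant pairs.
* **Layer c** — paired tests within all discordant pairs.
* **Layer d** — a mixed-model comparison of healthy co-twins of
  discordant pairs ("at risk") against all affected individuals,
  adjusting for individual-level covariates.
* **Layer e** — the same model on all healthy versus all affected
  individuals.

A feature is a candidate marker when it is flagged in every layer where
it was tested; `build_ledger()` records the feature-by-layer tick matrix.

# Statistical components

## Pairwise layers (a–c)

Within each discordant pair the affected-minus-healthy difference of the
feature (CLR genus abundance, log-z metabolite or pathway abundance) is
tested with the two-sided Wilcoxon signed-rank test. Zero differences are
discarded before ranking; with 25 or fewer non-zero tie-free differences
the exact null distribution is used, otherwise mid-ranks with the normal
approximation, tie correction and continuity correction. The direction of
association is the sign of the median within-pair difference.

No multiple-testing correction is applied inside layers a–c: these layers
are a raw-p screening step (`alpha = 0.05` for genera and metabolites,
`0.1` for the noisier predicted pathways), and error control is delegated
to the mixed-model layers. This is deliberate and is the main reason the
ledger, not any single layer, is the unit of inference.

## Zygosity-stratified linear mixed model (d–e)

The model underlying `fit_lmm()` is a Gaussian random-intercept model in
which the pair intercept variance depends on zygosity:

$$Y_i = \alpha_{z(j[i]),\,j[i]} + X_i\beta + \varepsilon_i,\qquad
  \varepsilon_i \sim N(0,\sigma^2),$$
$$\alpha_{MZ,j} \sim N(0,\sigma^2_{MZ}), \qquad
  \alpha_{DZ,j} \sim N(0,\sigma^2_{DZ}).$$

MZ pairs are expected to be more correlated than DZ pairs, so a single
shared intercept variance would misweight the two strata. The marginal
covariance is block diagonal with 2×2 pair blocks
$\sigma^2_z\mathbf{1}\mathbf{1}^\top + \sigma^2 I$, whose determinant and
inverse have closed forms; the likelihood is evaluated exactly in O(n)
and $\beta$ is profiled out by GLS at every variance evaluation. The
three variance components are optimized on the log scale (nonnegativity
by construction) by Nelder–Mead from five deterministic starting points
derived from the OLS residual variance, each polished by BFGS, keeping
the best optimum. Maximum likelihood is the default because it makes the
profiled likelihood directly comparable across models (REML is
available); fixed effects are tested by Wald z statistics.
`equal_pair_var = TRUE` constrains $\sigma^2_{MZ}=\sigma^2_{DZ}$, which
both recovers the generic single-variance random-intercept model (used as
an independent cross-check against `lme4` in the test suite) and permits
a likelihood-ratio test of whether zygosity-specific pair variance is
supported by the data.

`screen_features()` fits this model per feature with disease status as
the fixed effect of interest plus covariates (age, sex, BMI, antibiotics
use, vegetable and fruit intake by default; BMI can be dropped via the
`covariates` argument to reproduce a reduced covariate set), then applies
Benjamini–Hochberg step-up within the feature family. Families (genera,
metabolites, pathways) are corrected separately; conventional exploratory
thresholds are FDR < 0.2 for genera and metabolites and < 0.25 for
predicted pathways. Covariates that are constant within the analyzed
subset (e.g. sex in a nearly all-female cohort subset) are dropped with a
message rather than producing a singular design.

In the consistency ledger the d/e ticks are placed at raw p < 0.05 by
default, with FDR-level calls reported separately by the screen; this
mirrors the convention of tick-matrix figures in exploratory microbiome
studies where FDR-adjusted significance is reported alongside but the
cross-layer pattern is assembled from per-layer tests. `lmm_tick = "q"`
switches the ledger to FDR-based ticks.

## Preprocessing

Microbial counts: samples with fewer than 10,000 reads are excluded
(strictly less; a sample at the threshold is retained), then taxa
observed only once in the whole dataset, taxa present in only one sample,
all-zero taxa and empty samples are removed, in that order (the rules
overlap; the order only affects which rule the removal log attributes a
taxon to). Counts can be agglomerated to genus level through a
feature-to-genus map, with features unclassified at genus rank grouped as
"unclassified *family*". The centered log-ratio transform replaces zeros
by 0.5 — half the minimal observable count, the standard compositional
practice, exposed as `zero_replacement` — and maps each sample to
$\log x - \overline{\log x}$, so CLR rows sum to zero and the transform
is scale invariant.

Metabolites: features missing in strictly more than 25% of individuals
are dropped; remaining missing cells are imputed with the feature's
median of observed values; then `log(x + 1)`; then centering and scaling
to SD 1. This is the only order in which each step is well defined
(imputing after scaling would mix scales; logging before imputation would
bias the median for skewed panels). Scaling uses the population SD
(divisor n) by default — the convention is not universal, so
`sd_type = "sample"` is available; the package's own tests exercise the
population convention. Zero-variance features cannot be scaled and are
dropped with a warning. Covariates are imputed with the median (numeric)
or the mode with ties broken toward the no-exposure level (binary and
categorical).

## Dissimilarity comparisons

Bray–Curtis dissimilarity is computed on genus relative abundances
(CLR values can be negative and are not valid Bray–Curtis input);
metabolite profiles are compared by Euclidean distance on the log-z
scale. Distances are labeled within-pair versus outside-pair (outside
always excludes one's own co-twin) and by zygosity. Group comparisons use
Shapiro–Wilk (p > 0.05 on both groups routes to Student's t, otherwise
Wilcoxon rank-sum), two-sided. Two caveats are deliberate properties of
the procedure rather than bugs: pairwise distances sharing a sample are
not independent observations, so these p-values are descriptive; and for
groups above 5,000 values Shapiro–Wilk is evaluated on a deterministic
evenly spaced subsample (the test's implementation limit). Outside-pair
sets grow quadratically; `max_outside` offers a deterministic subsample
cap for very large cohorts, off by default.

## Correlation network

All differential genera × differential pathway pairs are correlated by
Spearman's rank correlation in the layer-d population, BH-adjusted as one
family across every computed pair, with edges retained at |rho| > 0.2 and
FDR < 0.05. rho is the Pearson correlation of mid-ranks (tie-corrected);
p-values use the exact distribution for n < 10 tie-free observations and
the t approximation otherwise. Because Spearman is rank-based, whether
genera enter on the CLR or relative-abundance scale is immaterial.

# The synthetic cohort generator

Restricted cohort data cannot ship with an analysis package, so every
stage is exercised against `simulate_cohort()`, whose defaults encode the
study conditions the pipeline assumes:

* **Structure** — 97 MZ + 122 DZ pairs (the canonical 219-pair cohort
  shape), one sequencing depth for all samples (20,000 reads; depth
  variation is not an analyzed factor).
* **Phenotype** — a liability-threshold model: each pair draws a
  bivariate standard-normal liability with correlation 0.8 (MZ) or 0.4
  (DZ) and thresholds it at `qnorm(1 - prevalence)` with prevalence 0.33.
  This is the simplest generative model that produces the MZ > DZ
  proband-concordance pattern; those defaults give expected proband-wise
  concordances near 0.6 (MZ) and 0.35 (DZ), verified in the tests against
  a quadrature oracle for the bivariate-normal orthant probability.
* **Counts** — log-normal-multinomial: per-genus baseline log-abundances
  (SD 1.5, giving a realistically uneven composition), a pair-shared
  Gaussian effect whose variance is larger for MZ (1.0) than DZ (0.6)
  pairs — reproducing the within-pair < outside-pair and MZ < DZ
  dissimilarity ordering — a disease shift on the spiked genera, and
  individual noise (variance 1.0), then a multinomial draw at the
  sequencing depth.
* **Metabolites** — the same latent structure, exponentiated so
  concentrations are positive and right-skewed, with missing-at-random
  masking (default 5% of cells; missing cells are `NA`, never zero).
* **Pathways** — noisy linear combinations of genus CLR values through a
  loading matrix, so genus–pathway rank correlations exist by
  construction and the network stage has a recoverable ground truth. The
  default loading assigns each pathway one driving genus.
* **Covariates** — age and sex shared within pair (97% female, age
  ~N(65, 7.7²)), BMI pair-correlated (~N(26.3, 4.7²), within-pair
  correlation 0.5), antibiotics Bernoulli(0.1), vegetable/fruit intake
  pair-correlated counts. A `leakage` switch adds a BMI shift per disease
  unit to create confounded features for testing covariate adjustment.
* **Effect sizes** — published studies of this design do not report
  effect sizes for their hits, so the spiked-genus effect is a
  testability choice, fixed once: 0.7 on the latent log scale, the value
  at which oracle simulation puts the layer-d FDR < 0.2 recovery power
  near 90% under the default configuration. The metabolite effect (0.8
  residual-SD units) is a comparable choice. Affected genera are drawn
  from the more abundant half of the baseline composition so the latent
  shift is not swamped by multinomial noise on rare taxa.

What the generator does **not** emulate: overdispersion beyond the
log-normal-multinomial (no zero inflation beyond sampling zeros),
phylogenetic correlation between genera, realistic metabolite pairwise
correlation structure (lipoprotein panels are strongly blocked),
longitudinal time points, or depth variation between samples. Passing
recovery tests on this generator therefore demonstrates that the
pipeline's inferential machinery is correct under its own model
assumptions, not that real cohort effects of a given size will be
detected at the same rates.

# Numerical choices and degenerate inputs

* CLR: zeros replaced by 0.5 before the log; empty samples are an error;
  per-sample CLR sums are zero to 1e-9.
* Signed-rank: all-zero difference vectors return p = 1 with direction 0;
  fewer than 6 usable pairs computes the exact test but warns about
  power.
* LMM: singular designs error naming the collinear columns; convergence
  is flagged; the optimality of the returned fit is spot-checked in the
  tests against random variance evaluations and a dense
  multivariate-normal oracle (agreement to 1e-8 on small cohorts).
* Proband-wise concordance `2C/(2C+D)` errors when no affected
  individuals exist; contingency tests fall back to Fisher's exact test
  when an expected cell is below 1 and error on degenerate tables.
* Chi-square tests report both Yates-corrected (default for 2×2) and
  uncorrected p-values; where a comparison can be counted per pair or per
  individual, both constructions are emitted, labeled. On the published
  219-pair table the individual-level constructions reproduce all four
  printed association p-values.
* Determinism: a fixed generator seed yields bit-identical cohorts, and
  `run_all()` output files are byte-identical across runs on the same
  input; mixed-model estimates are invariant to sample reordering and
  pair relabeling (deterministic optimizer starts, no RNG in fitting).

# Problem sizes used in the validation suite

The test and acceptance computations use cohorts of the default 219-pair
shape with 40–200 features and replicate counts of 50–200 per property
(100 replicates of 400 pairs for fixed-effect bias and coverage). These
sizes put Monte-Carlo error well below each assertion's tolerance while
keeping the whole suite comfortably reproducible on a laptop.

# Known limitations

* The pairwise layers deliberately report raw p-values; their output is a
  screening set, not an error-controlled discovery list.
* Wald tests on variance-component models can be slightly liberal for
  very small cohorts; the likelihood-ratio alternative is available by
  refitting nested models.
* The distance-comparison p-values treat pairwise distances as
  independent; they are not, and the package documents rather than
  corrects this (the convention for this comparison).
* With an effect calibrated to ~90% power in the well-powered layer d,
  the MZ-discordant layer (28 pairs) has materially lower power (~40%),
  so full five-layer consistency of a single spiked genus occurs in well
  under half of simulated cohorts. This is a structural property of the
  cohort's layer sizes, visible in the acceptance report's
  `spike_full_consistency_pct`, and mirrors the real design's reliance on
  the larger layers to confirm what the small pairwise layers suggest.
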