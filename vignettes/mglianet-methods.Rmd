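---
title: "Methods: microglial module networks for amyloid and tau pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microglial module networks for amyloid and tau pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Bulk cortical RNA-seq mixes the transcriptional output of every cell type
in the tissue. Groups of co-expressed genes ("modules") provide a
tractable intermediate: a module enriched for microglia-specific genes can
be read as a transcriptional program of microglia, and its per-sample
activity can be related to Alzheimer's-disease traits — amyloid burden,
tau burden, and the person-specific rate of cognitive decline — measured
in the same subjects. `mglianet` implements that analysis chain end to
end, together with two validation arms (single-nucleus RNA-seq and
quantitative microscopy of marker-stained microglia) and a synthetic
cohort generator with known ground truth, so every stage is testable
without access to restricted cohort data.

# Preprocessing and the module meta-feature

FPKM matrices are quantile normalized (each sample is mapped onto the
across-sample mean of the sorted columns; ties receive the mean of the
reference values at the tied ranks, which makes the transform idempotent),
optionally batch-adjusted by per-gene location/scale matching (each batch
re-centered and re-scaled to the pooled gene mean and pooled within-batch
standard deviation — the core of ComBat without its empirical-Bayes
shrinkage of batch parameters, a deliberate simplification), filtered to
genes with mean FPKM strictly above 1, log2-transformed as
`log2(FPKM + 1)` (the offset keeps zeros finite), and residualized
per gene on covariates by ordinary least squares.

The *meta-feature* of a module is the per-sample mean of the z-scored
(denominator n−1) expression of its member genes. It is invariant to
per-gene affine rescaling, so the exact normalization of individual genes
cannot leak into module-level results.

A design point worth making explicit: the pipeline residualizes expression
on *technical* covariates only (study, RIN, PMI). Age and sex are
adjusted inside the association models instead. Residualizing on age and
sex first would remove exactly the sex→module effects that the
association and network stages are meant to estimate.

# Signatures and enrichment

A cell-type signature is derived by the fold-change rule: a gene enters
the microglia set iff its mean FPKM in isolated microglia is at least 4×
its mean in every comparator profile (inclusive at exactly 4×; the rule's
wording is ambiguous and the inclusive reading is fixed here) and strictly
exceeds 1. Module enrichment uses the upper-tail hypergeometric test with
the post-filter gene universe as background and Bonferroni correction over
the module catalog. GWAS-proximal genes are flagged when a probe with
p < 0.05 (strict) lies within 50 kb of the gene (inclusive at exactly
50,000 bp), using 1-based inclusive intervals.

# Associations, slopes, and mediation

Module–trait associations are OLS fits of the trait on the meta-feature
with age, sex, study, RIN and PMI as default covariates; a cell-type-
adjusted variant adds other module meta-features as extra covariates.
P-values are two-sided throughout. Multiplicity is handled either by
Bonferroni (fixed threshold `alpha/m`) or Benjamini–Hochberg (the step-up
rule; the largest rejected p-value is reported as the data-dependent
threshold).

Cognitive-decline slopes come from a linear mixed model of longitudinal
global cognition with fixed effects for visit year, age, sex and
education and a correlated random intercept and slope per subject; the
reported slope is the conditional mode (BLUP), i.e. shrunken toward the
population mean. In the exactly-noiseless limit the mixed model is
degenerate and the implementation returns the (then exact) per-subject
OLS slopes.

Mediation uses the attenuation rule: A→B is *mediated* by C when the A
coefficient in `B ~ A + covariates` has p < 0.05 but rises above 0.05
once C enters the model. `order_triple()` runs the rule over all six
directed orderings of a triple and calls an ordering *supported* when the
outer pair is mediated while both inner links stay significant given the
remaining variable. No likelihood-based ranking is invented; ties are
reported, and outputs are labeled orderings *consistent with the data*,
never causal claims — cross-sectional data cannot establish causality.

# The partial-correlation network

Modules and traits are standardized and a sparse precision matrix is
estimated by the graphical lasso: maximize
`log det(Ω) − tr(SΩ) − λ Σ_{i≠j} |Ω_ij|` (diagonal unpenalized), solved
by block coordinate descent with warm starts along the penalty grid
(convergence tolerance 1e-4 on the working covariance relative to the
mean absolute off-diagonal of S; 500 sweeps maximum). Partial
correlations are `ρ_ij = −Ω_ij/√(Ω_ii Ω_jj)`; their zero pattern equals
Ω's. The penalty is tuned by repeated tenfold cross-validation of the
held-out Gaussian log-likelihood over 25 log-spaced values in
[0.01, 1]; within one standard error of the best mean score the largest
(sparsest) λ is chosen — the one-SE rule is this package's choice, since
only "repeated tenfold cross-validation" is prescribed by convention. The
standard error is the fold-level spread over √folds, as in `cv.glmnet`;
fold×repeat scores are dependent, so pooling them as independent draws
would understate the uncertainty and select an under-sparse penalty.
Technical covariates (RIN, PMI) enter the estimation as hidden nodes and
are suppressed from the reported edge list, so every reported edge is
conditional on them.

# Morphology

Cells are segmented from binary masks as 8-connected components
(components under 5 px discarded); coordinates are 0-based with centroids
at pixel centers. The ramification statistic is *compactness*: the
population variance of the pixel-to-centroid radial distances divided by
the area. The population-variance convention is a documented choice — the
defining phrase names only "variance". A filled disk scores lower than a
thin branched shape of equal area, so activated (ameboid) microglia score
low. Marker positivity is called per channel by a global Otsu threshold;
a cell is positive when at least 10% of its pixels exceed the threshold
(the required overlap fraction is unspecified in the source protocol;
10% is exposed as a parameter). Group differences in compactness use a
random-intercept-per-subject mixed model; the positive fraction is
related to ordinal stage scores (e.g. Braak) by OLS on the numeric score.

# Single-nucleus validation

Counts are CPM-normalized per cell (zero-count cells dropped with a
warning). The per-cell module score is the unweighted mean CPM over
*detected* module genes — no z-scoring, deliberately different from the
bulk meta-feature, because z-scores across sparse single-nucleus profiles
would be dominated by dropout. Per subject, the four microglial clusters'
proportions (relative to their sum) are computed, and one cluster's
proportion is related to tau burden by Huber robust regression (tuning
constant 1.345, 95% Gaussian efficiency — "robust linear regression" is
all that convention fixes) with sex and PMI as covariates.

# The synthetic cohort: what it emulates, and what it does not

`synthetic_truth()` fixes the study conditions once:

* Two causal chains on standardized scales: sex → m114 → amyloid →
  cognitive decline, and m5 → tau → cognitive decline, plus age → m116.
  Default coefficients: sex→m114 = 0.30, m114→amyloid = 0.30,
  m113→amyloid = 0.25, m5→tau = 0.30, tau→cogdec = −0.35,
  amyloid→cogdec = −0.25, age→m116 = 0.30. Sex is coded 0 = male,
  1 = female, with women higher on m5/m114; only magnitudes and the
  documented directions are meaningful, since a reference coding flips
  signs.
* Twelve modules of 30 genes (five microglial, four cell-type anchors,
  three background), gene loadings U(0.5, 1), per-gene log2 noise
  sd 0.6, log2 baselines N(3, 1.5). FPKM is generated on the log scale
  and exponentiated, so positivity holds by construction. Module-gene
  baselines are kept above the expression floor so planted signature
  overlap counts are deterministic; unassigned genes span the floor and
  exercise the filter.
* Half of each microglial module is planted in the microglia signature
  (all of m116). This is deliberately a *higher* fraction than a full-
  scale cohort would show: hypergeometric significance at a fixed overlap
  fraction decays as the background shrinks, so a ~400-gene scale-down
  must plant denser signatures to preserve the qualitative result (all
  five microglial modules enriched, cell-type modules not).
* Decline slopes have mean −0.05 and sd 0.10 per year, a realistic scale
  for annual global-cognition slopes in aging cohorts, and the scale at
  which mixed-model slope recovery at 8 visits with residual sd 0.25
  reaches reliability ≈ 0.87 (correlation ≈ 0.93 with truth).
* Pathology is generated Gaussian on the square-root scale (the scale on
  which such measures are approximately normal), then squared for the raw
  scale; ordinal stages (Braak, CERAD) are discretized from the latents.
* All randomness flows from one root seed through named child streams,
  one per output, so generating one output never perturbs another and
  identical truth gives byte-identical outputs.

The generator does **not** emulate read-level noise, library-size or GC
artifacts, LD structure in the GWAS arm, ambient RNA or doublets in the
single-nucleus arm, or spatial tissue context in the imaging arm. Passing
tests therefore demonstrate that the *statistical machinery* recovers
planted structure under idealized noise — not that it is robust to every
artifact of real data.

One calibration deserves honesty: with all causal paths capped at 0.35,
the marginal correlation between m5 activity and decline is at most
0.35 × 0.35 ≈ 0.12, so the attenuation-based mediation rule (which first
requires a significant marginal association) recovers the full
m5 → tau → decline ordering in only ~30–60% of simulated cohorts of 400
subjects; the reversal is essentially never supported. Detecting a
two-step chain by this rule needs either a stronger path product or a
larger cohort — a real limitation of attenuation-based mediation at
moderate effect sizes, which the package reports rather than hides.

# Numerical choices and degenerate inputs

* Quantile-normalization ties: mean of reference values over tied ranks.
* Graphical lasso at λ = 0 reduces to matrix inversion (verified against
  `solve()`); above the largest off-diagonal |S| the precision is exactly
  diagonal; block-diagonal S yields exactly block-diagonal estimates.
* The KKT residual of every fit is reported; tests hold it below 1e-4.
* Zero-variance genes are excluded from meta-features with a warning;
  constant channels make Otsu undefined and error; duplicated network
  nodes make S singular and error; subjects with no microglial cells are
  excluded from proportions with a warning.
* Exact zeros in Ω come from the soft-threshold step, not from rounding,
  so the edge set is well defined without an arbitrary cutoff.

# Problem sizes used by the test and acceptance suites

Simulated cohorts use 400 subjects and ~400 genes (the association,
network and mediation conditions), 150 subjects for null-calibration
batteries, 6 subjects × 600 cells for the morphology recovery run (60
cells per subject for its 20-seed null calibration), and 48 subjects ×
~7,200 nuclei for the single-nucleus arm — sizes chosen so the full suite
completes on a single CPU in minutes while keeping every recovery
property comfortably powered.

# Known limitations

* Batch adjustment lacks empirical-Bayes shrinkage; with very small
  batches, per-batch scale estimates are noisy.
* The mediation rule is the attenuation heuristic, not a counterfactual
  estimator; it cannot distinguish orderings whose regression structure
  is symmetric, and it reports such ties.
* The exact edge set of a cross-validated network depends on fold
  randomization; edge-level conclusions should be read across seeds, as
  the acceptance suite does.
* Module discovery itself (consensus clustering of co-expression) is out
  of scope: module assignments are consumed as input.
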