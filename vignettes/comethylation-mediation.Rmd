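---
title: "Co-methylation network mediation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-methylation network mediation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`comethmed` links a childhood family-emotional-health (FEH) questionnaire
score to fronto-limbic grey-matter volumes through saliva co-methylation
module eigengenes (MEs). This vignette documents the statistical models the
package implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The measurement scales

Methylation arrays report per-probe beta values, the proportion methylated
in `(0, 1)`. Betas are heteroskedastic near the boundaries, so analyses run
on M-values, `M = log2(beta / (1 - beta))`, after clipping betas to
`[eps, 1 - eps]` with `eps = 1e-6`. The clipping bound is the smallest value
that keeps M finite without visibly distorting the observed range of array
data; the transform and its inverse agree to `1e-10` away from the bounds.
Quantile normalization (ties averaged, via `limma`) forces each sample's
value distribution onto the across-sample mean of sorted vectors; it
preserves within-sample ranks and is idempotent.

Probe filters then remove X/Y-chromosome and rs-mapped probes (sex
comparability and genotype contamination) and, optionally,
cross-hybridizing probes supplied as an external id list. Finally the probe
universe is restricted to probes whose saliva values show a two-sided
Pearson correlation `p < 0.05` (t transform, `n - 2` df) with a paired
brain reference, because only cross-tissue-concordant probes can plausibly
proxy CNS methylation. At `alpha = 0.05` this filter passes ~5% of truly
independent probes — the retained set is enriched for concordance, not pure.

## Reference-free deconvolution

Saliva is a mixed tissue; composition differences confound probe-level
analyses. Without purified reference profiles, the package factorizes the
beta matrix of the top most-variable probes as `B ~ P F'`, with sample
mixing proportions `P` (rows on the simplex) and cell-type profiles `F`
(entries in `[0, 1]`), by alternating constrained least squares. Both block
updates are exact constrained minimizers (small active-set solvers with
enumeration fallbacks), which guarantees a non-increasing reconstruction
error — the property the test suite asserts. The objective is non-convex, so
10 random restarts are run and the lowest-error fit kept; components are
relabeled by descending mean proportion so output is deterministic. K = 5
cell types is the default, reflecting the saliva cell panel size this kind
of study uses; an explicit K is always a modeling assumption, and the
package keeps it a visible argument rather than auto-selecting.

Initialization draws are assigned to samples in sorted-id order, so the fit
is invariant to the row order of the input (up to row permutation).

## The co-methylation network

M-values are first residualized (per-probe OLS, intercept always included)
on age, sex, estimated cell proportions, and four genomic-ancestry
components. Because proportions sum to one, one component is dropped before
entering the design; the package refuses rank-deficient designs rather than
silently aliasing.

The network is unsigned: `A_ij = |cor_ij|^beta`. The soft threshold `beta`
is chosen as the lowest candidate whose signed scale-free fit (adjusted R^2
of `log10 p(k)` on `log10 k` over a 10-bin degree histogram, sign-flipped by
the slope) exceeds 0.90. When no candidate qualifies, the scan returns the
best-fitting power with a warning; the end-to-end pipeline instead falls
back to power 6, the conventional unsigned-network default, because the
arg-max fallback can select a power too low to separate modules from
background. The scale-free fit statistic is noisy at a few hundred probes;
this is a known limitation of degree-histogram fits, not of the data.

Topological overlap smooths adjacency by shared neighborhoods:
`TOM_ij = (l_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)` with
`l_ij = sum_u A_iu A_uj`, `TOM_ii = 1`, and dissimilarity `D = 1 - TOM`.
The implementation is validated against a literal triple-loop oracle to
`1e-10`.

Modules come from average-linkage clustering of `D` with a **static cut at
absolute height 0.99**, then dissolving clusters below 10 probes to the
unassigned label. Two open choices deserve a note:

* *Unsigned vs signed adjacency.* The historical default of weighted
  co-methylation analysis is unsigned, and the package follows it;
  anti-correlated probes co-cluster.
* *Cut rule.* A static cut at a fixed height on the `1 - TOM` scale was
  chosen over a quantile of merge heights: in noise-dominated dendrograms
  the height distribution concentrates near 1, so a quantile cut lands at
  the top of the tree and merges everything, while an absolute cut at 0.99
  leaves near-independent probes (D ~ 1) unmerged and preserves tight
  modules, which merge far below. The height is a visible argument.

Each module's eigengene is the first principal component of its
standardized probes, scaled to unit variance, with the sign chosen so the
ME correlates positively on average with its probes — making results stable
across linear-algebra backends.

## Association arms and multiplicity

Arm A regresses each regional volume on FEH with age, sex (female coded 1),
past-year stressful-life-events (SLE) score, four ancestry components, and
total brain volume (TBV) as covariates — 9 predictor terms plus intercept,
unstandardized coefficients, listwise deletion. Arm B regresses each ME on
FEH with SLE as the only covariate, since the other nuisance effects were
already removed by residualization (re-adjusting would double-count them).
Arm C mirrors Arm A with the ME replacing FEH as the focal predictor.
Dependent variables graduate to the next arm at `p < 0.05`; every non-TBV
model can be refit without TBV, mirroring dual reporting.

Benjamini-Hochberg control is step-up: with family size `m` and FDR `q`,
the i-th smallest p is compared with `i/m * q`, and every test up to the
largest passing rank is flagged. The family size is declared per analysis
(all non-intercept coefficients across a set of models — e.g. 8 volume
models x 9 terms = 72 in Arm A; 3 effects per mediation fit), and the
implementation accepts `m` larger than the number of supplied p-values so a
declared family can exceed the computed subset.

## Bootstrap mediation

For a mediator M, outcome Y, and exposure contrast `delta = treat -
control` on the FEH scale, the mediator model is the Arm B regression and
the outcome model is the Arm A regression plus the mediator term:

* `IDE = a * b * delta` (a: FEH slope of the mediator model; b: mediator
  slope of the outcome model),
* `DE = c' * delta` (c': FEH slope of the outcome model),
* `TE = IDE + DE`, exactly, because the models are linear with no
  exposure-mediator interaction. An interaction term would break this
  additivity, so the package deliberately omits one.

Uncertainty comes from a nonparametric case-resampling bootstrap: subjects
are resampled with replacement and both models refit per draw (default
10,000 draws in study use; tests scale this down). Confidence intervals
are the 2.5/97.5 bootstrap percentiles — percentile rather than
bias-corrected intervals, since the simple percentile rule is the most
transparent choice for a sum-decomposed triplet. The two-sided bootstrap p
is `2 * min(Pr(draw <= 0), Pr(draw >= 0))`, floored at `1/(B + 1)` so a
finite resample never reports p = 0. Rank-deficient resamples are redrawn
and counted.

The default exposure contrast runs from the observed minimum FEH (poorest)
to the observed maximum, so effects read as "volume difference under poor
vs high exposure"; both endpoints are arguments. Classification follows the
CI rule: an effect is "nonzero" when its 95% CI excludes 0; *full*
mediation means IDE and TE nonzero with DE not; *partial* means all three
nonzero. Probe-wise follow-up inside full-mediator modules applies the same
machinery with each residualized probe as the mediator, with the BH family
equal to 3 x probe count, and reports each probe's correlation with its ME.

## Enrichment

Probe-wise association regresses FEH on each residualized probe M-value
with SLE as covariate. The default mode places independent zero-mean normal
priors (SD 3 on standardized slopes — weakly informative at the scale where
a standardized slope of 3 would explain most of the score's variance) on
all non-intercept coefficients, with a plug-in residual variance and a
two-sided normal posterior-tail p; a flat-prior mode reproduces the OLS
t-test exactly and anchors the oracle tests. Cell-heterogeneity covariates
are *not* re-entered by default, because the residual matrix already
removed them (a visible toggle exists for the double-adjustment variant).

Gene scores adjust for probe coverage: a gene's score is the Sidak-adjusted
minimum probe p, `1 - (1 - min_p)^n_probes`, removing the advantage of
genes with many probes. Gene sets are intersected with the scored universe,
kept when their effective size is in `[50, 1000]` (dropping sparse sets and
high-level catch-all terms), and tested by a one-sided rank-sum comparison
of `-log(gene score)` in-set vs out-of-set (exact tail when feasible).
Redundancy reduction sweeps results by ascending p and drops any set whose
Jaccard gene overlap with a retained set exceeds 0.5. This scoring chain is
a transparent probe-count-aware analog of methylation-aware enrichment
tools, and is labeled as such; it is not a reimplementation of any specific
tool's internal model.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` and `generate_methylation()` produce seeded cohorts at
the default study conditions: 98 subjects aged 18-22, 69% female; an FEH
score summing 70 binary items from a single-factor probit model calibrated
to mean 60, SD 8.5 (one latent liability rather than 70 item prevalences,
which are unknown — item difficulty is a free parameter); an SLE score tied
linearly to the FEH latent to hit a target correlation of -0.44, truncated
at 0; regional volumes with means/SDs on the scale reported for young-adult
cohorts (e.g. right amygdala 1859 [210] mm^3), a TBV component so the TBV
covariate is
non-trivial, a direct FEH slope, and module-mediated effects through latent
module scores. Default planted effects are `a_effect = 0.05` latent units
per FEH unit, `b_effect = 60` mm^3 per latent unit, and `c_direct = 7`
mm^3 per FEH unit — sized so the planted total effect is ~10 mm^3 per FEH
unit with ~30% mediated, the magnitude regime this analysis operates in.

Methylation is built on the M scale: three planted 20-probe modules load on
their latent scores; 30% of probes are cell-type markers with one dominant
cell-specific effect (SD 3 on the M scale) plus minor effects, mixed
through Dirichlet proportions with substantial subject-to-subject
variation; background probes get heterogeneous noise (0.5-4x the nominal
SD), reproducing the heavy-tailed per-probe variance of real arrays in
which the most variable sites reflect composition and intrinsic
variability rather than any single co-methylation module. This matters:
reference-free deconvolution consumes the most-variable probes, and if
planted modules dominated that pool the estimated proportions would absorb
the module latents and residualization would erase the signal — a leakage
regime real studies avoid simply because modules are a negligible share of
a full array. The generator emulates that share, not the full array size.

Deliberately planted filter targets (X/Y/rs/cross-hybridizing probes) and
an out-of-range gene-set pair exercise the preprocessing and enrichment
filters. The paired cross-tissue reference adds M-scale noise to a flagged
fraction of probes and draws the rest independently with matched moments.

Not emulated: raw array intensities and detection p-values, batch and
chip effects, genotypes, smoking exposure, MRI images, and probe-probe
linkage within genes. Passing tests therefore demonstrate correct recovery
of planted linear-Gaussian structure at realistic sizes and noise — they do
not certify behavior under batch confounding or non-linear exposure
effects.

## Numerical choices and degenerate inputs

* Variance ties in probe selection break by probe id; module renumbering
  ties break by first-appearing probe; both make output order-independent.
* Constant probes are refused (network, eigengenes, probe association) or
  dropped with a warning (cross-tissue filter) rather than silently
  propagating NaN.
* The deconvolution convergence rule is a relative Frobenius improvement
  below `1e-6`, or an error below `1e-7` of the data norm (noiseless
  mixtures drive the error to machine precision, where relative
  improvements never shrink).
* Fewer probes than the minimum module size yields an all-unassigned
  module set, not an error; an empty mediation candidate list yields an
  empty report.

## Problem sizes in the test suite

Unit tests run on cohorts of 98 subjects and a few hundred probes; recovery
and coverage suites use 50-100 replicates (planted-module recovery at the
default 1200-probe configuration; mediation CI coverage at n = 200 with
1,000 bootstrap draws; the null-retention simulation over 10,000 probe
pairs). These sizes were chosen to make the Monte-Carlo assertions stable
while keeping a full test run around a minute on one core.

## Known limitations

* The static cut has no concept of nested modules; a dynamic tree cut can
  split large heterogeneous clusters that the static cut keeps whole.
* The scale-free fit is unstable below ~500 probes; the pipeline's power-6
  fallback covers the failure mode but is a convention, not an estimate.
* Reference-free proportions are identified only up to the factorization's
  ambiguities; with correlated cell types or few samples, components mix.
* Mediation here is statistical: sequential ignorability is assumed, not
  tested, and no sensitivity analysis is provided.
* BH control is applied within declared families; the gating itself (p <
  0.05 graduation) is exploratory and inflates the family-wise error of
  the full chain, exactly as in the study design it follows.
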