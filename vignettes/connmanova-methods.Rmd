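---
title: "Multivariate group inference for regional connectome metrics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate group inference for regional connectome metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connmanova)
```

## The problem

A case-control neuroimaging study measures five regional metrics —
cortical area, cortical thickness, mean curvature, gray-matter volume and
white-matter connectivity density (CD) — on a common parcellation of the
brain (165 parcels by default), in a cohort of autism-spectrum cases and
typically-developing controls of both sexes recruited at several
acquisition sites. The scientific question is whether sex, diagnosis, or
specifically their *interaction* (the term that encodes a sex-dependent
disease effect) shapes any of these metric panels, and if so, in which
brain regions. `connmanova` implements this inference as a four-step
multivariate procedure around a `ConnectomeExperiment` container (a
`SummarizedExperiment` whose assays are the metric panels, with the cohort
in `colData` and the parcel atlas in `rowData`).

## Preprocessing

**TICV normalization.** Every regional value is divided by the subject's
total intracranial volume, removing head-size scaling. The division is
applied to all five metrics, following the source procedure literally even
though thickness and curvature are not volumetric; `ticvNormalize()`
accepts a `metrics` argument as the per-metric opt-out.

**Confound residualization.** Age, acquisition site (dummy-coded), a
selection of DAS intelligence scales (GCA by default — the general-ability
composite is the natural single summary when only "intelligence" is
specified; all five scales are selectable) and their interactions are
projected out of each parcel column by least squares
(`residualizeConfounds()`). The phrase "interaction between the three" is
ambiguous, so the default design uses all pairwise products plus the
age x site x DAS three-way product; `"threeway"`, `"pairwise"` and
`"none"` are available. Residuals are exactly orthogonal to the confound
columns and the operation is idempotent.

Only the response panels are residualized; the hypothesis design keeps its
raw ±1 codes. Two consequences matter and are discussed under
*Calibration* below: the error degrees of freedom are optimistic by the
confound rank (the `adjust_df` flag in `confoundSpec()` enables honest
accounting; the default `FALSE` matches the source convention
`vE = N - q - 1`), and any component of a hypothesis predictor lying in
the confound column span leaks into the error SSCP.

**Quadratic age.** Before the main analysis, `quadraticAgeTest()` fits the
confound model with and without an `age^2` column and converts the partial
Wilks lambda of the deleted column to an exact partial F on
`(p, vE - p + 1)` degrees of freedom, per metric, with Benjamini-Hochberg
correction across the 5-metric family (the smallest faithful reading of
"after correction for multiple comparisons"). The pipeline includes
`age^2` in the confound design only when this test rejects.

## The four steps

Let `Y` (subjects x parcels) be one residualized metric panel and `X` the
design with intercept, sex (+1 male / -1 female), diagnosis (+1 case / -1
control) and their product, so `q = 3`.

**Step 1 (omnibus).** `fitMvReg()` computes the least-squares coefficients
and the hypothesis/error SSCP matrices `H` and `E` (`H + E` equals the
total corrected SSCP; this identity is asserted throughout the tests).
Wilks' lambda `det(E)/det(E + H)` is evaluated through Cholesky
log-determinants — at p = 165 the determinants themselves overflow — and
converted by Rao's approximation
(`t = sqrt((p^2 vH^2 - 4)/(p^2 + vH^2 - 5))`, `w = vE + vH - (p+vH+1)/2`,
`d1 = p vH`, `d2 = w t - (d1-2)/2`) to an F statistic; at the study
dimensions (p = 165, vH = 3, vE = 189) this yields the familiar
`d1 = 495`, `d2 -> 76` pair. BH-FDR is applied across the 5 metrics and
only rejected metrics advance.

**Step 2 (predictor leave-one-out).** Each predictor is deleted in turn;
the partial lambda is the ratio of the full-model lambda to the reduced
one. A single deleted predictor admits the exact transform
`F = ((1 - L)/L) (vE - p + 1)/p` on `(p, vE - p + 1)` df. Published
analyses of this design have printed the `(q, vE - p)` pair instead; the
output carries both conventions (`df1`/`df2` and `df1_alt`/`df2_alt`) so
either can be compared. BH-FDR runs across the 3 predictors.

**Step 3 (CCA).** `ccaFit()` whitens both blocks through Cholesky factors
of `S_yy` and `S_xx` and takes the SVD of the whitened cross-covariance;
singular values are the canonical correlations (clamped to [0, 1] against
roundoff, response-side coefficients sign-fixed so their
largest-magnitude entry is positive). The CCA form of Wilks' statistic is
`prod(1 - r_k^2)`, identical to the determinant ratio of Step 1, so the
predictor leave-one-out in the CCA frame (`predictorLooStep3()`)
reproduces Step 2's decisions exactly — the package tests this identity to
1e-10. Forming `S_yy^-1 S_yx S_xx^-1 S_xy` explicitly is avoided: at
p = 165 with N = 193 the whitened route is the numerically stable one.
When `S_yy` is near-singular (p approaching N) the Cholesky guard fails
with guidance rather than silently regularizing.

**Step 4 (region leave-one-out).** Each parcel is removed in turn
(`p' = p - 1` responses remain) and its partial lambda is converted by the
exact single-response transform `F = ((1 - L)/L)(vE - p + 1)/vH` on
`(vH, vE - p + 1)` df. Because both lambdas are determinant ratios, the
per-parcel partials reduce to `((E+H)^-1)_jj / (E^-1)_jj`, evaluated from
two matrix inversions rather than 165 reduced fits; tests verify the
identity against brute-force dual Wilks evaluations to 1e-12. BH-FDR runs
across parcels and the critical partial F at the FDR level is reported,
the tabular analogue of a thresholded cortical-surface rendering.

## The synthetic generator

`syntheticSpec()` encodes the study conditions as defaults: 110 cases (55
female) and 83 controls (40 female); four sites with near-uniform mixing;
ages uniform on 7-18 years; the five DAS scales multivariate normal with
the published per-group means and standard deviations and cross-scale
correlation 0.7 (the published scales are strongly redundant); TICV normal
per group (212.94 +/- 30.07 vs 217.56 +/- 25.94 cm^3, truncated positive).
Metric panels are a deterministic per-parcel baseline gradient plus age,
site and DAS effects in noise-sd units (slopes 0.3, offsets +/-0.3, slope
0.2 — moderate confound structure of the kind the residualization stage
exists to remove), plus Gaussian noise with exchangeable inter-parcel
correlation 0.2. Every value is scaled by the subject's relative TICV so
head size enters multiplicatively and normalization removes it exactly.
The sex-by-diagnosis interaction `delta * sex * diagnosis` (noise-sd
units) is planted on 22 bilateral temporal/parietal target parcels of the
CD panel only.

What the generator does *not* emulate: structured (non-exchangeable)
inter-parcel covariance, site-specific scaling or nonlinearity, non-normal
measurement error, and spatially graded effect profiles. Real cortical
data have strongly structured covariance with low effective rank; this
matters for power, as the next section explains, so passing or failing
simulation-based checks here speaks to the specified generating model,
not to real-data behaviour.

## Calibration findings and limitations

Three empirical findings from the package's own simulations
(`inst/scripts/calibrate-delta.R` and the acceptance suite) deserve
emphasis.

**Omnibus power at p = 165 plateaus far below common expectations.** With
N = 193 subjects and vE = 189 error df, the error SSCP is barely
well-conditioned (p/vE = 0.87) and the omnibus F has only d2 = 76
denominator df. An interaction effect confined to 22 of 165 parcels is
diluted across 143 noise dimensions, and — because only the responses are
residualized — the part of the interaction code lying in the confound
column span (about 6% of its variance under the default design) stays in
the error SSCP and grows as `delta^2`. The measured Step-1 power curve
rises to roughly 0.15-0.2 near `delta = 3` and then flattens; no `delta`
reaches the 0.9 power the calibration originally targeted. The frozen
default `calibratedDelta() = 3` is the plateau onset under the
calibration script's pre-stated selection rule.

**The region-wise leave-one-out test cannot rank a perfectly uniform
effect.** When an identical `delta * sex * diagnosis` term is planted on
all 22 target parcels, removing any single target is almost fully
compensated by the remaining 21: the conditional noncentrality saturates
near N/21 regardless of `delta`. Top-22 recovery by Step-4 partial F
therefore sits near the chance level 22/165 at the calibrated effect
size. A spatially varying effect profile, or correlated-but-distinct
per-parcel effects, would be needed for Step 4 to rank regions the way it
evidently does on real data, where regional effects are never exactly
collinear.

**The default df convention is approximately, not exactly, calibrated.**
Under the full null the default pipeline rejects at about 0.04 per metric
instead of 0.05: the hypothesis SSCP is slightly deflated because the ±1
design is not orthogonal to the projected-out confound span, while the
optimistic `vE = N - q - 1` convention deflates the error mean square by
about the same factor, leaving a mildly conservative net size. Enabling
`adjust_df` removes only the second bias and makes the test markedly more
conservative; exact size would require residualizing the design columns as
well (a Frisch-Waugh construction), which the reproduced procedure does
not do. The package keeps the procedure faithful and documents the size.

## Numerical choices

- Determinant ratios: Cholesky log-determinants; a factor with a relative
  pivot below `sqrt(.Machine$double.eps)` aborts with advice to reduce the
  response dimension (no silent ridge regularization).
- Rao's `t` falls back to 1 when `p^2 vH^2 <= 4`, reproducing the exact
  special cases (`p <= 2` or `vH <= 2`).
- Eigen-solution route for CCA: whiten-and-SVD; deterministic sign
  convention on the coefficient vectors.
- Ties and degenerate inputs: zero-variance columns, empty factorial
  cells, non-finite cells and rank-deficient confound designs all fail
  with named-column errors rather than producing output.
- Problem sizes in the shipped checks: the null-calibration study runs
  1000 replicates at p = 30, N = 100 and the planted-effect study 200
  replicates at the full p = 165, N = 193; both finish in a few minutes
  on one CPU and the vE/p geometry of the full design is preserved in the
  second.

## A worked run

```{r example, eval = FALSE}
cfg <- pipelineConfig(spec = syntheticSpec(delta = calibratedDelta()),
                      seed = 11)
rep <- runPipeline(cfg, verbose = TRUE)
rep$step1
writeReport(rep, "results/run1")
```

The report directory contains one TSV per analysis stage (the Step-4
table sorted descending by partial F), a `report.json` with provenance
(package version, seed, configuration hash) and a hash manifest;
re-exporting an unchanged report reproduces identical hashes.
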