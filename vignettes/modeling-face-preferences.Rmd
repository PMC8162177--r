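---
title: "Modeling individual face-preference models by reverse correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling individual face-preference models by reverse correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`prefcorr3d` treats a face stimulus as a point in a generative morphable
space: a categorical average (one per ethnicity-by-sex cell at a fixed age)
plus an identity residual expressed through orthonormal bases — one basis for
3D shape over the mesh vertices, and one band-limited basis per
spatial-frequency (SF) octave for the L\*a\*b\* complexion map. Rendering is
affine in the coefficients:

$$\text{mesh} = \bar{M}_{\text{cell}} + B_s\, c_s, \qquad
  \text{texture} = \bar{T}_{\text{cell}} + \sum_b B_{c,b}\, c_{c,b}.$$

An observer rates each randomly drawn face on a 9-point attractiveness
scale. Reverse correlation then fits, independently per identity dimension
$j$,

$$c_j = \beta_{1,j} + \beta_{2,j}\,\text{rating} + \varepsilon$$

by robust linear regression. The $\beta_2$ map across all dimensions is that
observer's *preference model*: the direction in face space along which faces
look more attractive to them. Everything downstream — group averaging,
extreme-face reconstruction, the dimorphism cosine test, the PCA
representation space, the variance decomposition, cross-validated prediction
— operates on these models.

The central assumption is **linearity** of the coefficient–rating relation.
Two diagnostics probe it: `check_linearity()` (bin-average faces over five
rating bins, per-vertex distance profiles, k-means clustering of those
profiles, and each centroid's deviation from the straight line joining its
endpoints) and `fit_mi_model()` (a Gaussian-copula mutual-information model,
sensitive to any monotone dependence, signed by the regression slopes and
compared to the linear model by Spearman correlation against a
magnitude-shuffle null).

## The synthetic generator and what it does (not) emulate

The package ships no face data. `build_generative_space()` constructs a
structurally faithful stand-in for a morphable-model database: smooth seeded
cell averages (a Fibonacci-sphere head mesh with low-order polynomial
deformations; smooth low-frequency L\*a\*b\* fields with per-cell tints),
a column-orthonormalized Gaussian shape basis, and complexion bases built by
band-pass-filtering random textures before orthonormalization, so each band
basis reconstructs only its stated octave. Simulated raters carry a planted
linear preference $w$; their rating drive is
$\langle w, c\rangle + \mathcal{N}(0, \sigma^2)$, mapped monotonically onto
the 9 rating levels.

What this emulates: the average-plus-orthonormal-residual structure, the
shared residual set across ethnic averages (coefficients are stored
cell-free), equal-count use of the rating scale, and a known ground truth
for every recovery test. What it does not emulate: real facial geometry and
texture statistics, nonlinear or non-monotone human preferences, peaked
("ideal point") preferences, viewpoint effects (viewpoint is carried as a
nuisance column and never influences simulated ratings), or inter-rater
correlation structure beyond what the cohort generator plants. Passing tests
therefore certify the *estimators and inference machinery*, not claims about
real faces.

## Key parameter choices

- **Desk scale** (defaults of `space_config()`): 500 vertices, 40 shape
  dimensions, 80×60 texture grid, 40 complexion dimensions in each of 5 SF
  bands. Every analysis, including 13-fold cross-validation and
  bootstrap/permutation inference, runs in seconds to a few minutes at this
  scale; the full-study scale (4,735 vertices, 467 dimensions, 800×600
  pixels) is available via `paper_scale_config()` for dimension bookkeeping
  (`space_dim_summary()`), since its complexion bases alone would need tens
  of gigabytes to instantiate.
- **Coefficient sampling in SD units.** Stimulus coefficients are drawn
  i.i.d. standard normal per dimension (`coeff_scale = 1`), the common
  morphable-model convention in which the basis carries the geometry and
  coefficients are expressed in units of each component's natural SD. This
  choice matters: the reverse regression estimates
  $\beta_{2,j} \propto w_j \,\mathrm{Var}(c_j)$, so only unit sampling
  variance makes the fitted $\beta_2$ *direction* a consistent estimate of
  the planted preference. Under decaying sampling scales the recovery cosine
  would cap near 0.87 regardless of trial count — an identifiability
  artifact, not an estimator property. The space separately carries a
  decaying *database eigenvalue spectrum* ($\lambda_j = j^{-1.2}$) used only
  to rank dimension importance for elbow-based reduction.
- **Rating link.** Drives map to ratings by empirical quantiles into 9
  equal-count bins. Ties share a bin (rank with `ties.method = "min"`), so a
  constant drive yields a single rating level; for continuous drives the
  link is strictly monotone and uses the full scale.
- **SNR convention.** `noise_sd_for_snr(space, rater, snr)` sets the noise
  SD so that (drive SD)/(noise SD) equals `snr`; the study conditions use
  SNR 2 with 1,950 trials per rater.
- **Robust fit.** Bisquare IRLS with tuning constant 4.685, scale
  $\mathrm{median}|r|/0.6745$, at most 50 iterations, tolerance $10^{-8}$ —
  the standard defaults of robust fitting routines. All dimensions share the
  two-column design, so the weighted normal equations are solved in closed
  form by column sums; slope p-values come from the final weighted
  least-squares step ($t$, $n-2$ df), a documented approximation.
- **Rating bins for the linearity check**: the 9 levels collapse to
  {1–2, 3–4, 5, 6–7, 8–9}; k-means uses 20 restarts over $k = 1..8$ with the
  elbow on within-cluster dispersion.
- **Attractive-set rule for z-scoring**: ratings ≥ 8, falling back to a
  participant's top decile when that set is empty; the modal coefficient is
  the peak of a Gaussian kernel density (Silverman bandwidth, 512-point grid
  over the observed range).
- **Bootstrap and permutation sizes**: 1,000 bootstrap resamples for the
  cosine test by default (tests and the acceptance script use 200 for
  runtime), 20 bootstrap models per participant for the variance
  decomposition, 200 permutations for null thresholds at the Bonferroni
  percentile $100 - 100\alpha/k$ per component (99.375 for 8 components at
  $\alpha = 0.05$; 98.33 for 3).
- **Validation GLM**: Gamma family with log link (ratings are positive and
  right-skewed), IRLS with at most 100 iterations, tolerance $10^{-8}$;
  folds are a random permutation of trials into 13 contiguous blocks under a
  recorded seed.

## Numerical and design decisions

Several choices were genuinely open; the package resolves them as follows.

- **Signed linearity distances.** The per-vertex distance profile projects
  each bin's deviation onto that vertex's dominant direction of travel (its
  bin-5 minus bin-1 deviation), falling back to the unsigned norm where that
  direction is degenerate. An unsigned norm would make any symmetric linear
  preference look V-shaped (the middle bin's average face sits at the
  categorical average), defeating the diagnostic's purpose. Note also that
  with the quantile rating link the bin means of a Gaussian drive sit ~8.5%
  off the endpoint chord even for an exactly linear rater — the outer bins
  stretch into the tails — so "near-linear" means deviations of that order
  plus bin-mean sampling noise, with monotone centroids.
- **Elbow method.** The retained index maximizes perpendicular distance to
  the chord joining the first and last eigenvalues; distances below
  $10^{-12}$ of scale are treated as exact zeros so a perfectly linear decay
  resolves to the first index deterministically.
- **Variance decomposition from zero.** `SStotal` is measured from 0, the
  no-effect point of a β2 score, not from the grand mean. Weighted summaries
  normalize the retained components' explained-variance weights to sum to 1.
- **Permutation calls.** In group mode the permutation unit is the
  participant — their bootstrap models move together across conditions; in
  participant mode conditions stay fixed and models shuffle within
  condition. Two significance summaries are reported: per-component flags at
  the Bonferroni percentile (the familywise call, calibrated to ~5% under
  the null) and the weighted-sum-of-thresholds overall call, which is
  deliberately conservative.
- **Stimulus projection in validation.** Stimulus residuals are measured
  from the categorical average (the origin of identity space), so they are
  projected onto the model-PCA loadings *without* subtracting the model
  mean; model vectors themselves are centered before PCA.
- **Paired-test unit.** Predictor families are compared by participant mean
  τ across folds (folds within a participant are dependent), with Bonferroni
  correction over the 4 comparisons.
- **Transfer classification.** Locations where the other-ethnicity model
  shares signs with both reference models are reported as their own class
  (`both`) rather than double-counted; zero slopes match nothing.
- **Group-level cosine intervals.** Where a group-level bootstrap summary is
  needed, bootstrap iterations are averaged iteration-wise across
  participants rather than pooled.

## Degenerate inputs

Constant ratings raise a degenerate-design error; dimensions with zero
residual scale fall back to plain least squares within the IRLS; zero
stimulus SD at a location flags the z-score as undefined (`NA`) rather than
zero; a zero-norm direction raises an error in cosine and projection
computations; empty rating bins name the offending bin; ragged or
out-of-range trial tables fail with row numbers.

## Problem sizes used by the test suite

The suite and `scripts/acceptance.R` run at desk scale: 40 raters × 1,950
trials for parameter recovery; 1,000 random cases for the FDR and elbow
oracles; 200 simulations × 200 permutations for null calibration; 20 seeds
per arm for the bootstrap-cosine calibration; an 80-model cohort (4
conditions × 20 raters, 650 trials each, 4 bootstrap models per rater) for
the representation space; and 20 cohorts of 9 raters for the
cross-validated predictor ordering. These sizes were chosen so the full
pipeline exercises every stage in minutes on one CPU.

## Known limitations

Linear preference models only — no interaction terms, peaked preferences, or
viewpoint-specific models. The synthetic bases have no facial semantics, so
vertex-level maps are only meaningful relative to the synthetic space. The
MI model uses a Gaussian-copula estimator, which lower-bounds MI and is
blind to non-monotone dependence that a histogram estimator might detect.
Robust-fit p-values are asymptotic weighted-LS approximations. The KDE mode
of a sharply truncated attractive set sits near the selection boundary, so
modal z-scores for simulated *linear* raters are bounded by the selection
quantile — more extreme modal features require peaked or real preferences.
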