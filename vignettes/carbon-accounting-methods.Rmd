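---
title: "Methods: carbon-flux mapping and UNSEEA account compilation"
author: "seeaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon-flux mapping and UNSEEA account compilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `seeaflux`, the
choices made where the problem admitted several defensible designs, what
the synthetic-landscape generator does and does not emulate, and the
limitations a user should keep in mind.

## The estimation problem

The quantity of interest is the signed net above-ground carbon flux
z(s) (Mg C ha⁻¹) of each 1-ha pixel over an accounting period, observed
at a set of reference plots (field inventory or repeated-LiDAR pixels)
and predicted everywhere else from covariate rasters. The account needs,
per UNSEEA ecosystem class: the opening stock, the net flux and the
closing stock, each in Tg C with a standard deviation. Three statistical
sub-problems follow: (1) a regression with heteroscedastic, weighted
observations; (2) a per-pixel predictive distribution, not just a mean;
(3) aggregation of correlated per-pixel errors to class totals.

## Stacked ensemble with quantile meta learner

Three base-learner families are fixed: bagged regression trees (random
forest via `ranger`), gradient-boosted trees (`xgboost`), and a kernel
regressor. Each is tuned by grid search minimizing 5-fold CV RMSE
(case-weighted fitting, unweighted scoring; ties resolved
first-in-grid). The default grids are deliberately small, published-style
grids: trees {250, 500} × candidate-feature fraction {√p, p/3}; boosting
depth {3, 6} × learning rate {0.05, 0.1} at 200 rounds; kernel cost
{1, 10} × bandwidth {0.5, 1, 2} × the median pairwise distance
heuristic.

The kernel learner is a *weighted kernel ridge regression*: with
standardized inputs, the coefficient vector solves
(K + λ W⁻¹) α = y − ȳ_w, where K is the RBF Gram matrix, λ = 1/cost and
W the diagonal case-weight matrix, so heavier plots incur proportionally
larger loss. This gives the margin-style regressor an exact,
closed-form, weight-respecting fit; support-vector regression as
implemented in the common R packages cannot weight individual
observations in regression mode.

Stacking uses a single 5-fold partition per master seed. Base learners
trained on k−1 folds predict the held-out fold, producing a strictly
out-of-fold n × 3 prediction matrix; the meta learner — a random forest
with retained leaf response distributions (`quantreg` mode) and case
weights — is trained on that matrix only. No raw covariates enter the
meta level, so the meta learner can only reweight and smooth the base
predictions, which is what makes its fold-honest error estimates
meaningful. Deployment base learners are refit on all data.

Per-pixel 5th/95th quantiles of the meta forest's leaf-pooled response
distribution bound a 90% prediction interval. The SD layer divides the
interval width by 2 × 1.645 (the Gaussian 90% identity). A literal mode
multiplying the half-width by 1.64 is retained because published
accounts have used that form; it inflates the SD by a factor of about
2.7 and is therefore not the default.

Case weights are inverse measurement variances normalized to mean 1, so
the effective sample size (and the learners' default behaviour) is
unchanged. A caution worth stating: when measurement SD is proportional
to |flux|, near-zero-flux plots receive very large weights and can
dominate the bootstrap; the variance floor (1 Mg C ha⁻¹ by default)
bounds this but does not remove it. This is a property of
inverse-variance weighting itself, not of the implementation.

## Cross-validation and importance

Model skill is reported as the unweighted mean ± SD over five folds of
RMSE, ME (observed − predicted) and R² = 1 − SSE/SST, with SST taken
about the fold-local mean of the observations (the metric definitions
are silent on pooling; fold-local is the conservative choice).
Each fold's model is a full refit, including the nested base/meta
discipline, so no information leaks from the scored fold.

Covariate importance permutes each covariate (one seeded shuffle per
covariate × fold; one-hot blocks of a categorical covariate move
jointly) in the held-out fold and records the RMSE increase, averaged
over folds. Per-learner scores are combined with weights equal to the
meta learner's own permutation importance of each base-prediction
column, then rescaled so the top covariate scores 100. Category shares
divide summed scores by the total; super-categories separate the global
biomass products (CCI, Flux, AGB, CONUS tags) from other dynamic inputs
(environmental dynamics, land cover) and static inputs (management,
topography, climate).

## Feature-space coverage

Predictions in covariate-space regions far from any training plot are
extrapolations. Each retained continuous covariate is standardized by
the training mean/SD and scaled by its normalized importance; the
dissimilarity index of a pixel is its Euclidean distance to the nearest
plot in this space divided by the mean pairwise distance among plots.
Categorical covariates are excluded — Euclidean distance on indicator
codes would dominate the metric. The under-sampling threshold is
Q3 + 1.5 IQR of the training plots' own cross-validated DI (distance to
the nearest plot outside the plot's fold), the conventional
upper-whisker rule. Coverage fractions are computed on the retained
covariate set, after collinearity screening, because that is the space
the model actually predicts in.

## GLCM textures

The texture window is 3 × 3 cells (300 m at the 100 m working
resolution). Windows are quantized into 32 equal-width bins over the
layer's *global* finite range — not per-window ranges, so textures are
comparable across the map and invariant to affine rescaling that
preserves bin assignment. The co-occurrence matrix pools the four
offsets (0,1), (1,0), (1,1), (1,−1), symmetrized and normalized; mean,
variance, homogeneity and contrast follow the standard definitions with
1-based level indices. Windows touching the raster edge or any missing
cell are nodata. A constant layer maps to a single level (homogeneity 1,
contrast 0) by construction. Direction set, level count and edge
handling are fixed conventions of this package; the statistics
themselves are the standard ones.

## Variograms and error aggregation

Standardized residuals (z − ẑ)/SD at plot cells feed a Matheron
empirical variogram with equal-width distance bins (zero-distance pairs
excluded, empty bins omitted, default maximum distance half the domain
diagonal). An exponential model γ(h) = nugget + psill(1 − e^(−h/r)) is
fitted by pair-count-weighted least squares (`minpack.lm`), reporting
the effective range 3r. Two numerical safeguards matter: the range
parameter is bounded below by the first lag midpoint (the nugget/sill
split below the first observed distance is not identifiable), and the
structured model is kept only when it improves on a pure-nugget fit by a
5%-level F-test on the weighted residual sums of squares — otherwise the
fit collapses to pure nugget (ρ ≡ 0), which is also the non-convergence
fallback.

Class variances sum pairwise covariances σᵢⱼ = ρ(hᵢⱼ)·SDᵢ·SDⱼ over the
class mask, with ρ(0) = 1 and ρ truncated to zero beyond the effective
range. The truncation makes the double sum computable exactly as a sum
over integer cell offsets within the range window — each offset
contributes ρ(h) times a shifted elementwise product of the SD grid — so
the correlated mode costs O(cells × offsets) rather than O(cells²). The
independent mode (Σ SDᵢ²) is the default for country-scale accounts,
where fitted ranges of a few kilometres are negligible relative to class
extents; the correlated mode exists for small regions where they are
not. Closing-stock variance adds the aggregated opening and flux
variances, assuming the two error sources are independent.

## Accounts

Land cover is reclassified to the six UNSEEA Level-2 classes through a
mapping table, with nearest-neighbour resampling of coarser sources
(integer-ratio replication onto the working grid) and a plantation
overlay that overrides natural-forest labels. Flux is signed; the
closing stock is opening + signed flux per pixel, so the identity
closing = opening + net flux holds exactly at class and total level by
linearity. Net emissions (negative pixels) and net sequestration
(positive pixels) partition the flux; zero-flux pixels contribute to
neither. Emissions are attributed by the land-cover transition:
forest → forest is degradation, forest → non-forest is conversion, and
emissions on pixels not forest in the opening epoch (possible in the
other-woody class) fall in an explicit unattributed column so the
partition stays exhaustive. Sequestration is not attributed.

## The synthetic landscape

The generator exists so that every stage has a testable ground truth.
Covariates are stationary Gaussian random fields (Gaussian-kernel
smoothing of white noise, re-standardized; the kernel SD is the stated
correlation length), the true flux is a linear combination of the
covariates plus Gaussian noise (optionally spatially correlated), land
cover is an equal-quantile partition of a latent field with a
configurable fraction of forest pixels converted in the closing epoch,
and plots are sampled under uniform, systematic or clustered designs
with measurement SD = cv × max(|flux|, 1). Default conditions — 100 m
cells, six covariates at 1000 m correlation length, coefficients
(8, −6, 4, −2, 1, 0) (signal SD ≈ 11 Mg C ha⁻¹), noise SD 5.5
(2:1 signal-to-noise), 20% relative opening-stock SD — are fixed once as
a realistic regional flux-mapping regime and used unchanged in all
tests.

What the generator does *not* emulate: radar backscatter physics and
signal saturation in dense forest, LiDAR waveform processing,
plot geolocation error, non-stationary covariate relationships, and
real countries' spatial patterns. Passing tests therefore demonstrate
that the estimation machinery is correct and well calibrated under its
own assumptions — linear signal, Gaussian errors, stationarity — not
that real-data accuracy will match the synthetic figures.

## Problem sizes and numerical conventions

The test and acceptance runs use a 200 × 200 landscape with 1000 plots
for ensemble recovery (the recovery claims are medians over consecutive
scenario seeds, since individual landscape draws vary), 500 scattered
points for variogram recovery, 40 × 40 landscapes with 60 plots for the
sampling-design comparison, and the 100 × 100 demonstration pipeline —
sizes at which all statistical behaviour of interest is already visible.
All randomness flows from explicit integer seeds through a deterministic
stage-seed derivation; the quantile forest's terminal-node sampling is
additionally executed under a pinned RNG state, so identical
configurations reproduce byte-identical outputs. Degenerate inputs are
handled explicitly: constant rasters quantize to one gray level,
zero-variance observations make R² undefined (reported missing, with a
warning), all-identical plots give a zero coverage threshold, zero plot
variances are refused with a pointer to the variance floor, and
q05 > q95 anywhere is an error naming the pixel.

## Known limitations

Rasters are held in memory as dense matrices, suiting country-scale
work at the tested resolutions but not continental mosaics; grids are
exchanged as Esri ASCII text. k-fold CV is random, not spatial: with
strongly clustered reference data it is known to flatter map accuracy,
and intensity-weighted or spatial CV would be the appropriate
extension. Sampling variability (as opposed to residual variability) is
not propagated into class SDs. One pooled variogram is fitted per map
rather than per stratum, and the opening-stock residual standardization
reuses the flux procedure.
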