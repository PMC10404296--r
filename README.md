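# seeaflux

National-scale mapping of net forest carbon flux with quantified
uncertainty, and compilation of UNSEEA ecosystem carbon accounts from the
resulting maps.

Countries reporting under the UN System of Environmental-Economic
Accounting (UNSEEA) need, per ecosystem class and accounting period, an
opening carbon stock, the net flux (sequestration positive, emission
negative) and a closing stock — each with a standard deviation. When
repeated in-situ measurements exist (national forest inventory plots,
repeated airborne-LiDAR biomass maps), the net above-ground carbon flux
can be mapped directly by regressing the observed plot-level flux z(s) on
spatially exhaustive covariates (multi-date biomass products, height and
tree-cover dynamics, vegetation indices, land cover, terrain), and the
per-pixel map then aggregated to UNSEEA classes. `seeaflux` implements
that full chain for analysts building such accounts, plus a synthetic
landscape generator with known truth so every stage is testable without
any external data.

## Method

* **Reference preparation** — quality filtering (forest-change and
  LiDAR-edge flags), biomass-to-carbon conversion (carbon fraction 0.49),
  plot-variance models, and inverse-variance case weights
  `w_i ∝ 1/σ_i²`, normalized to mean 1.
* **Covariates** — gray-level co-occurrence (GLCM) texture layers (mean,
  variance, homogeneity, contrast; 3 × 3 cells ≙ 300 m window, 32 gray
  levels, pooled symmetric 4-direction matrix), collinearity screening of
  |r| > 0.8 pairs on 5000 sampled pixels (the land-cover epoch pair is
  exempt), and point-in-cell extraction into a design matrix with one-hot
  categorical expansion.
* **Feature-space coverage** — a dissimilarity index
  DI(s) = d(s, nearest plot) / mean pairwise plot distance, computed in
  the importance-weighted standardized covariate space; pixels with
  DI above the training-set threshold Q3 + 1.5 IQR are reported as
  under-sampled, overall and per UNSEEA class.
* **Prediction** — a stacked ensemble: bagged trees (random forest),
  gradient-boosted trees, and a weighted kernel ridge regressor as base
  learners, each grid-search tuned by 5-fold CV RMSE; a quantile-capable
  random forest meta learner trained strictly on out-of-fold base
  predictions. Prediction intervals come from the meta learner's leaf
  response distributions (quantile regression forest, 5th/95th
  percentiles), and the per-pixel SD from the 90% interval width:
  SD = (q95 − q05)/(2 × 1.645) (a literal mode reproducing the published
  (width/2) × 1.64 form is available).
* **Evaluation** — five-fold cross-validation with
  RMSE = √(Σ(z−ẑ)²/n), ME = Σ(z−ẑ)/n and R² = 1 − SSE/SST, plus
  fold-permutation covariate importance aggregated over learners and
  covariate categories.
* **Error aggregation** — standardized residuals r(s) = (z−ẑ)/SD(s) at
  plot locations, Matheron empirical variograms, weighted least-squares
  exponential correlogram fits ρ(h), and class-level variances
  SD_class = √(ΣᵢΣⱼ ρ(h_ij)·SDᵢ·SDⱼ) with an independent mode
  (ρ ≡ 0 beyond negligible ranges) and exact windowed summation in the
  correlated mode. Closing-stock variance adds opening and flux variances
  under independence.
* **Accounts** — land-cover reclassification to the six UNSEEA Level-2
  classes (plantation mask overrides natural forest), per-class
  opening/flux/closing totals in Tg C, emission/sequestration split, and
  attribution of emissions to forest degradation (forest → forest) versus
  conversion (forest → non-forest).

## Worked example

```r
library(seeaflux)

spec  <- scenario_spec(grid_shape = c(100L, 100L), n_plots = 400L, seed = 42)
scn   <- simulate_scenario(spec)
refset <- compute_case_weights(estimate_plot_variance(filter_plots(scn$plots)))
stack  <- covariate_stack(scn$covariates)
design <- extract_at_plots(stack, refset)

model <- fit_stacked_ensemble(design, seed = 42)
summary(model)
#> Stacked carbon-flux ensemble
#> flux_ensemble: 3 base learners + quantile meta forest (n = 400)
#>   bagged_trees             meta weight 0.29
#>   gradient_boosted_trees   meta weight 0.43
#>   kernel_margin            meta weight 0.28
#>   out-of-bag fit: RMSE 9.25, ME -0.20, R2 0.51

pred     <- predict_ensemble(model, stack)        # mean, q05, q95, SD layers
classmap <- reclassify_landcover(scn$landcover_2018, scn$plantation_mask)
totals   <- class_totals(scn$opening_stock, pred$mean_flux, classmap)
splits   <- emissions_split(pred$mean_flux, classmap,
                            scn$landcover_2010, scn$landcover_2018)
build_account_table(totals, splits = splits)
#> UNSEEA carbon account (Tg C; negative flux = net emission)
#>   broadleaved    area         23 km2 | opening 0.22 | flux -0.00 | closing 0.22
#>   coniferous     area         23 km2 | opening 0.23 | flux -0.00 | closing 0.23
#>   mixed          area         16 km2 | opening 0.15 | flux 0.00 | closing 0.15
#>   other_woody    area         32 km2 | opening 0.32 | flux 0.00 | closing 0.33
#>   plantation     area          8 km2 | opening 0.07 | flux 0.00 | closing 0.07
#>   total          area        100 km2 | opening 1.00 | flux 0.00 | closing 1.00
```

The meta weights are the meta learner's permutation importance of each
base learner's predictions; the out-of-bag RMSE/ME/R² are honest in both
stacking levels (base predictions are out-of-fold, meta predictions
out-of-bag). The account rows satisfy closing = opening + net flux exactly;
on this small demonstration landscape the per-class fluxes round to 0.00 Tg
at two decimals.

`run_pipeline(default_config(seed = 1), out_dir = "out")` executes the
whole chain (simulate → prepare → covariates → tune/fit → evaluate →
predict → coverage → aggregate → account) and writes every artifact plus a
run manifest; re-running an identical config reproduces identical numbers.
A thin CLI wrapper lives in `inst/cli/seeaflux.R`
(`seeaflux.R run-all --seed 1 --out DIR`).

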