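test_that("grid tuning selects the better hyperparameters deterministically", {
  # data generated by a deep interaction: a shallow boosted model is
  # provably worse than a deep one
  set.seed(41)
  n <- 400
  X <- matrix(runif(n * 4, -1, 1), n, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 10 * (X[, 1] > 0) * (X[, 2] > 0) * (X[, 3] > 0) + rnorm(n, sd = 0.3)
  d <- structure(list(X = X, response = y, weights = rep(1, n),
                      coords = data.frame(x = 1:n, y = 1:n),
                      plot_id = as.character(1:n),
                      covariates = colnames(X),
                      kind_tags = stats::setNames(rep("continuous", 4),
                                                  colnames(X)),
                      category_tags = stats::setNames(rep("envi", 4),
                                                      colnames(X)),
                      encoding = list()), class = "design_matrix")
  spec <- learner_spec("gradient_boosted_trees",
                       list(nrounds = 100, max_depth = c(1, 6), eta = 0.3))
  tuned <- tune_base_learner(spec, d, k = 5, seed = 9)
  expect_equal(tuned$tuned_values$max_depth, 6)
  tuned2 <- tune_base_learner(spec, d, k = 5, seed = 9)
  expect_identical(tuned$tuned_values, tuned2$tuned_values)

  # single-combination grid returns that combination
  s1 <- tune_base_learner(
    learner_spec("kernel_margin", list(cost = 10, bw_mult = 1)), d)
  expect_equal(s1$tuned_values$cost, 10)
})

test_that("stacking handles constant, oracle and shuffled responses", {
  sp <- scenario_spec(grid_shape = c(40, 40), n_plots = 150, n_covariates = 2,
                      flux_coefficients = c(6, -3), noise_sd = 0,
                      measurement_cv = 0, seed = 43)
  fx <- make_design(sp)

  # constant response -> near-constant predictions
  dz <- fx$design
  dz$response <- rep(0, nrow(dz$X))
  mz <- fit_stacked_ensemble(dz, quick_specs(), seed = 1)
  pz <- predict(mz, dz$X)
  expect_lt(max(abs(pz$mean)), 1e-6)

  # oracle learner: the true flux is available as a covariate in the
  # noise-free scenario, so the stack must interpolate almost perfectly
  m <- fit_stacked_ensemble(fx$design, quick_specs(), seed = 1)
  # meta out-of-bag predictions on the out-of-fold base matrix
  expect_gt(compute_metrics(fx$design$response,
                            m$meta_learner$predictions)$r2, 0.85)

  # constructed oracle: a design whose only covariate IS the true flux —
  # the stack must pass it through nearly unchanged
  do <- fx$design
  do$X <- cbind(truth = fx$design$response)
  do$weights <- rep(1, nrow(do$X))
  do$covariates <- "truth"
  do$kind_tags <- c(truth = "continuous")
  do$category_tags <- c(truth = "envi")
  mo <- fit_stacked_ensemble(do, quick_specs(), seed = 1)
  expect_gt(compute_metrics(do$response, mo$meta_learner$predictions)$r2,
            0.99)

  # shuffled response -> no skill
  dn <- fx$design
  set.seed(2)
  dn$response <- sample(dn$response)
  r2s <- vapply(1:3, function(s) {
    mn <- fit_stacked_ensemble(dn, quick_specs(), seed = s)
    compute_metrics(dn$response, mn$meta_learner$predictions)$r2
  }, numeric(1))
  expect_true(all(r2s <= 0.1))
})

test_that("prediction propagates nodata and preserves geometry", {
  sp <- scenario_spec(grid_shape = c(30, 30), n_plots = 100, n_covariates = 2,
                      flux_coefficients = c(6, -3), seed = 44)
  fx <- make_design(sp)
  m <- fit_stacked_ensemble(fx$design, quick_specs(), seed = 1)
  stack2 <- fx$stack
  stack2$layers$cov1$values[5, 7] <- NA
  pred <- predict_flux(m, stack2)
  expect_equal(dim(pred), c(30L, 30L))
  expect_true(is.na(pred$values[5, 7]))
  expect_false(anyNA(pred$values[-5, ]))
  # missing layer is named in the error
  stack3 <- fx$stack
  stack3$layers$cov2 <- NULL
  expect_error(predict_flux(m, stack3), "cov2")
})

test_that("quantile maps bound the median and collapse at equal levels", {
  sp <- scenario_spec(grid_shape = c(40, 40), n_plots = 200, n_covariates = 2,
                      flux_coefficients = c(8, -4), noise_sd = 4, seed = 45)
  fx <- make_design(sp)
  m <- fit_stacked_ensemble(fx$design, quick_specs(), seed = 1)
  q <- predict_quantiles(m, fx$stack, levels = c(0.05, 0.95))
  expect_true(all(q[[1]]$values <= q[[2]]$values + 1e-9, na.rm = TRUE))
  qm <- predict_quantiles(m, fx$stack, levels = c(0.5, 0.5))
  expect_equal(qm[[1]]$values, qm[[2]]$values)
  med <- predict_quantiles(m, fx$stack, levels = c(0.5, 0.95))[[1]]
  ok <- mean(q[[1]]$values <= med$values & med$values <= q[[2]]$values,
             na.rm = TRUE)
  expect_gte(ok, 0.99)
  expect_error(predict_quantiles(m, fx$stack, levels = c(0, 0.95)),
               "parameter error")
})

test_that("permutation importance ranks signal over noise and normalizes", {
  sp <- scenario_spec(grid_shape = c(50, 50), n_plots = 250, n_covariates = 3,
                      flux_coefficients = c(10, 0, 0), noise_sd = 1,
                      measurement_cv = 0.02, seed = 46)
  fx <- make_design(sp)
  m <- fit_stacked_ensemble(fx$design, quick_specs(), seed = 1)
  imp <- permutation_importance(m, fx$design)
  expect_equal(max(imp$per_covariate), 100)
  expect_equal(names(which.max(imp$per_covariate)), "cov1")
  # pure-noise covariates stay below 5% of the top score (5 seeds)
  for (s in 2:5) {
    ms <- fit_stacked_ensemble(fx$design, quick_specs(), seed = s)
    is_ <- permutation_importance(ms, fx$design)
    expect_lt(max(is_$per_covariate[c("cov2", "cov3")]), 5)
  }
  expect_error(permutation_importance(structure(list(fold_fits = NULL),
                                                class = "flux_ensemble"),
                                      fx$design),
               "state error")
})

test_that("category aggregation produces unit-sum shares", {
  imp <- structure(list(per_covariate = c(a = 60, b = 60, c = 0),
                        per_base = NULL, base_weights = NULL),
                   class = "importance_table")
  tags <- c(a = "CCI", b = "envi", c = "topo")
  agg <- aggregate_importance(imp, tags)
  expect_equal(sum(agg$per_category), 1)
  expect_equal(unname(agg$per_category[c("CCI", "envi")]), c(0.5, 0.5))
  expect_equal(unname(agg$per_supercategory["global-AGB-maps"]), 0.5)
  expect_equal(unname(agg$per_supercategory["other-dynamic"]), 0.5)
  expect_equal(unname(agg$per_supercategory["static"]), 0)
  # single loaded category takes share 1
  imp2 <- structure(list(per_covariate = c(a = 100, b = 0)),
                    class = "importance_table")
  agg2 <- aggregate_importance(imp2, c(a = "Flux", b = "LC"))
  expect_equal(unname(agg2$per_category["Flux"]), 1)
  expect_error(aggregate_importance(imp, c(a = "CCI")), "untagged")
})

test_that("full-run determinism under a fixed master seed", {
  sp <- scenario_spec(grid_shape = c(30, 30), n_plots = 80, n_covariates = 2,
                      flux_coefficients = c(5, -2), seed = 47)
  fx <- make_design(sp)
  m1 <- fit_stacked_ensemble(fx$design, quick_specs(), seed = 99)
  m2 <- fit_stacked_ensemble(fx$design, quick_specs(), seed = 99)
  expect_identical(m1$oof, m2$oof)
  p1 <- predict_ensemble(m1, fx$stack)
  p2 <- predict_ensemble(m2, fx$stack)
  expect_identical(p1$mean_flux$values, p2$mean_flux$values)
  expect_identical(p1$q95$values, p2$q95$values)
})
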