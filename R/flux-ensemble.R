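#' Base-learner specification
#'
#' The ensemble uses three fixed base-learner families: bagged regression
#' trees (random forest), gradient-boosted trees, and a kernel regressor
#' (weighted radial-basis kernel ridge regression, whose ridge penalty
#' plays the role of the margin cost and whose per-observation loss is
#' scaled by the case weights). `hyper_grid` holds one value list per
#' hyperparameter; [tune_base_learner()] fills `tuned_values` with the
#' grid combination minimizing k-fold CV RMSE.
#'
#' @param family one of `"bagged_trees"`, `"gradient_boosted_trees"`,
#'   `"kernel_margin"`.
#' @param hyper_grid named list of candidate value vectors; defaults per
#'   family are small published-style grids.
#' @param tuned_values named list of selected values (normally filled by
#'   tuning).
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(family = c("bagged_trees", "gradient_boosted_trees",
                                    "kernel_margin"),
                         hyper_grid = NULL, tuned_values = NULL) {
  family <- match.arg(family)
  if (is.null(hyper_grid)) {
    hyper_grid <- switch(family,
      bagged_trees = list(num_trees = c(250, 500), mtry_frac = c(NA, 1 / 3)),
      gradient_boosted_trees = list(nrounds = 200, max_depth = c(3, 6),
                                    eta = c(0.05, 0.1)),
      kernel_margin = list(cost = c(1, 10), bw_mult = c(0.5, 1, 2)))
  }
  if (!length(hyper_grid)) stop("hyper_grid must be non-empty")
  structure(list(family = family, hyper_grid = hyper_grid,
                 tuned_values = tuned_values),
            class = "learner_spec")
}

#' Default base-learner specifications for the stacked ensemble
#'
#' @return list of three [learner_spec()]s (bagged trees, gradient
#'   boosted trees, kernel regressor).
#' @export
default_learner_specs <- function() {
  list(learner_spec("bagged_trees"),
       learner_spec("gradient_boosted_trees"),
       learner_spec("kernel_margin"))
}

# ---- single-learner fit/predict -------------------------------------------

fit_one_learner <- function(family, X, y, w, params, seed) {
  if (is.null(w) || all(is.na(w))) w <- rep(1, length(y))
  switch(family,
    bagged_trees = {
      p <- ncol(X)
      mtry <- if (is.na(params$mtry_frac)) max(1L, floor(sqrt(p)))
              else max(1L, floor(p * params$mtry_frac))
      fit <- with_seed(seed,
        ranger::ranger(x = as.data.frame(X), y = y,
                       num.trees = params$num_trees, mtry = mtry,
                       case.weights = w, seed = seed, num.threads = 1))
      list(family = family, fit = fit)
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
      list(family = family, fit = fit)
    },
    kernel_margin = fit_krr(X, y, w, cost = params$cost,
                            bw_mult = params$bw_mult),
    stop("unknown learner family: ", family))
}

predict_one_learner <- function(model, X) {
  switch(model$family,
    bagged_trees = predict(model$fit, data = as.data.frame(X),
                           num.threads = 1)$predictions,
    gradient_boosted_trees = predict(model$fit, xgboost::xgb.DMatrix(X)),
    kernel_margin = predict_krr(model, X))
}

# Weighted RBF kernel ridge regression. Inputs are standardized by the
# training mean/SD; the bandwidth is `bw_mult` times the median pairwise
# distance among (up to 500) training points; the ridge penalty is
# 1/cost, divided per observation by its case weight so that heavier
# plots incur larger loss for the same residual.
fit_krr <- function(X, y, w, cost = 1, bw_mult = 1) {
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  n <- nrow(Z)
  sub <- if (n > 500) Z[seq(1, n, length.out = 500), , drop = FALSE] else Z
  med <- stats::median(stats::dist(sub))
  sigma <- max(bw_mult * med, 1e-8)
  K <- exp(-as.matrix(stats::dist(Z))^2 / (2 * sigma^2))
  ybar <- stats::weighted.mean(y, w)
  lambda <- 1 / cost
  alpha <- solve(K + lambda * diag(1 / w, n), y - ybar)
  list(family = "kernel_margin", Z = Z, mu = mu, sdv = sdv, sigma = sigma,
       alpha = alpha, intercept = ybar)
}

predict_krr <- function(model, X) {
  Z <- sweep(sweep(X, 2, model$mu), 2, model$sdv, "/")
  d2 <- outer(rowSums(Z^2), rowSums(model$Z^2), "+") - 2 * Z %*% t(model$Z)
  d2[d2 < 0] <- 0
  drop(exp(-d2 / (2 * model$sigma^2)) %*% model$alpha) + model$intercept
}

# ---- tuning ----------------------------------------------------------------

#' Grid-search tuning of a base learner
#'
#' Scores every combination of the hyperparameter grid by k-fold CV RMSE
#' (case-weighted fitting, unweighted RMSE) and selects the minimizer;
#' ties break in first-in-grid order. Combinations that fail to fit score
#' +Inf and are reported. Deterministic given the seed.
#'
#' @param spec a [learner_spec()].
#' @param design a [extract_at_plots()] design matrix.
#' @param k folds.
#' @param seed integer seed.
#' @return the `learner_spec` with `tuned_values` filled and a
#'   `tuning_rmse` attribute holding the per-combination scores.
#' @export
tune_base_learner <- function(spec, design, k = 5, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  grid <- expand.grid(spec$hyper_grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 1) {   # nothing to choose; skip the CV scoring
    spec$tuned_values <- as.list(grid[1, , drop = FALSE])
    return(spec)
  }
  folds <- kfold_split(nrow(design$X), k = k, seed = derive_seed(seed, 21L))
  scores <- rep(Inf, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    sse <- 0; n_tot <- 0; failed <- FALSE
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- tryCatch(
        fit_one_learner(spec$family, design$X[tr, , drop = FALSE],
                        design$response[tr], design$weights[tr], params,
                        seed = derive_seed(seed, 1000L + g * k + f)),
        error = function(e) NULL)
      if (is.null(fit)) { failed <- TRUE; break }
      pred <- predict_one_learner(fit, design$X[!tr, , drop = FALSE])
      sse <- sse + sum((design$response[!tr] - pred)^2)
      n_tot <- n_tot + sum(!tr)
    }
    if (failed) {
      message(sprintf("tune_base_learner: combination %d failed to fit", g))
    } else {
      scores[g] <- sqrt(sse / n_tot)
    }
  }
  best <- which.min(scores)   # first minimum = first-in-grid tie break
  spec$tuned_values <- as.list(grid[best, , drop = FALSE])
  attr(spec, "tuning_rmse") <- cbind(grid, rmse = scores)
  spec
}

# ---- stacking --------------------------------------------------------------

#' Fit the stacked ensemble
#'
#' For each of `k` folds, the three base learners are trained on the
#' remaining folds and predict the held-out fold, producing a strictly
#' out-of-fold 3-column prediction matrix. The meta learner — a
#' quantile-capable bagged-trees model (random forest with retained leaf
#' response distributions) with case weights — is trained on that matrix
#' only (no raw covariates). The base learners are then refit on all data
#' for deployment.
#'
#' @param design a [extract_at_plots()] design matrix.
#' @param specs list of 3 [learner_spec()]s; untuned specs are tuned
#'   first.
#' @param k folds (the same partition serves tuning, stacking, and
#'   importance).
#' @param seed integer master seed.
#' @param meta_trees trees in the meta forest.
#' @return object of class `flux_ensemble`.
#' @export
fit_stacked_ensemble <- function(design, specs = default_learner_specs(),
                                 k = 5, seed = 1L, meta_trees = 500) {
  n <- nrow(design$X)
  if (n < 2 * k) stop("need at least 2k observations to stack")
  specs <- lapply(specs, function(s) {
    if (is.null(s$tuned_values)) tune_base_learner(s, design, k = k, seed = seed)
    else s
  })
  fam <- vapply(specs, `[[`, character(1), "family")
  folds <- kfold_split(n, k = k, seed = derive_seed(seed, 31L))
  oof <- matrix(NA_real_, n, length(specs),
                dimnames = list(NULL, paste0("base_", fam)))
  fold_fits <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fold_fits[[f]] <- lapply(seq_along(specs), function(b) {
      fit_one_learner(fam[b], design$X[tr, , drop = FALSE],
                      design$response[tr], design$weights[tr],
                      specs[[b]]$tuned_values,
                      seed = derive_seed(seed, 2000L + f * 10L + b))
    })
    for (b in seq_along(specs)) {
      oof[!tr, b] <- predict_one_learner(fold_fits[[f]][[b]],
                                         design$X[!tr, , drop = FALSE])
    }
  }
  w <- design$weights
  if (is.null(w) || all(is.na(w))) w <- rep(1, n)
  # quantreg ranger also consumes the R-level RNG (terminal-node response
  # sampling), so the fit runs under a pinned RNG state
  meta <- with_seed(derive_seed(seed, 41L),
    ranger::ranger(x = as.data.frame(oof), y = design$response,
                   num.trees = meta_trees, case.weights = w,
                   quantreg = TRUE, seed = derive_seed(seed, 41L),
                   num.threads = 1))
  base <- lapply(seq_along(specs), function(b) {
    fit_one_learner(fam[b], design$X, design$response, w,
                    specs[[b]]$tuned_values, seed = derive_seed(seed, 3000L + b))
  })
  names(base) <- fam
  # meta-level permutation importance of each base-prediction column
  meta_pred0 <- predict(meta, data = as.data.frame(oof),
                        num.threads = 1)$predictions
  rmse0 <- sqrt(mean((design$response - meta_pred0)^2))
  d_rmse <- vapply(seq_along(specs), function(b) {
    shuf <- oof
    shuf[, b] <- with_seed(derive_seed(seed, 4000L + b), sample(shuf[, b]))
    p <- predict(meta, data = as.data.frame(shuf),
                 num.threads = 1)$predictions
    sqrt(mean((design$response - p)^2)) - rmse0
  }, numeric(1))
  b2m <- pmax(d_rmse, 0)
  if (sum(b2m) == 0) b2m <- rep(1, length(specs))
  b2m <- b2m / sum(b2m)
  names(b2m) <- fam
  structure(list(
    base_learners = base, meta_learner = meta, specs = specs,
    fold_assignment = folds, fold_fits = fold_fits, oof = oof,
    base_to_meta_importance = b2m,
    columns = colnames(design$X), covariates = design$covariates,
    kind_tags = design$kind_tags, category_tags = design$category_tags,
    encoding = design$encoding,
    train_response = design$response, seed = seed
  ), class = "flux_ensemble")
}

#' @export
print.flux_ensemble <- function(x, ...) {
  cat(sprintf("flux_ensemble: %d base learners + quantile meta forest (n = %d)\n",
              length(x$base_learners), length(x$train_response)))
  for (nm in names(x$base_learners)) {
    cat(sprintf("  %-24s meta weight %.2f\n", nm,
                x$base_to_meta_importance[[nm]]))
  }
  invisible(x)
}

#' @export
summary.flux_ensemble <- function(object, ...) {
  # meta forest OOB predictions on the out-of-fold base matrix: honest in
  # both stacking levels; heavily weighted plots can be in-bag in every
  # tree and then have no OOB prediction
  oob <- object$meta_learner$predictions
  ok <- is.finite(oob)
  m <- compute_metrics(object$train_response[ok], oob[ok])
  cat("Stacked carbon-flux ensemble\n")
  print(object)
  cat(sprintf("  out-of-bag fit: RMSE %.2f, ME %.2f, R2 %.2f\n",
              m$rmse, m$me, m$r2))
  invisible(list(oof_metrics = m))
}

#' Predict from a fitted ensemble
#'
#' @param object a [fit_stacked_ensemble()] model.
#' @param newdata numeric matrix with the training column layout; rows
#'   with any `NA` yield `NA`.
#' @param type `"mean"`, `"quantiles"` or `"both"`.
#' @param levels quantile levels in (0, 1).
#' @param ... unused.
#' @return list with `mean` and/or a matrix `quantiles`.
#' @export
predict.flux_ensemble <- function(object, newdata,
                                  type = c("mean", "quantiles", "both"),
                                  levels = c(0.05, 0.95), ...) {
  type <- match.arg(type)
  if (any(levels <= 0 | levels >= 1)) {
    stop("parameter error: quantile levels must be inside (0, 1)")
  }
  if (!identical(colnames(newdata), object$columns)) {
    miss <- setdiff(object$columns, colnames(newdata))
    if (length(miss)) stop("missing covariate columns: ",
                           paste(miss, collapse = ", "))
    newdata <- newdata[, object$columns, drop = FALSE]
  }
  ok <- stats::complete.cases(newdata)
  basep <- matrix(NA_real_, nrow(newdata), length(object$base_learners),
                  dimnames = list(NULL, colnames(object$oof)))
  if (any(ok)) {
    for (b in seq_along(object$base_learners)) {
      basep[ok, b] <- predict_one_learner(object$base_learners[[b]],
                                          newdata[ok, , drop = FALSE])
    }
  }
  out <- list()
  if (type %in% c("mean", "both")) {
    out$mean <- rep(NA_real_, nrow(newdata))
    if (any(ok)) {
      out$mean[ok] <- predict(object$meta_learner,
                              data = as.data.frame(basep[ok, , drop = FALSE]),
                              num.threads = 1)$predictions
    }
  }
  if (type %in% c("quantiles", "both")) {
    q <- matrix(NA_real_, nrow(newdata), length(levels),
                dimnames = list(NULL, sprintf("q%02.0f", 100 * levels)))
    if (any(ok)) {
      q[ok, ] <- predict(object$meta_learner,
                         data = as.data.frame(basep[ok, , drop = FALSE]),
                         type = "quantiles", quantiles = levels,
                         num.threads = 1)$predictions
    }
    out$quantiles <- q
  }
  out
}

# Chunked stack prediction shared by predict_flux / predict_quantiles.
predict_over_stack <- function(model, stack, type, levels = c(0.05, 0.95)) {
  miss <- setdiff(model$covariates, names(stack$layers))
  if (length(miss)) stop("missing covariate layer: ", paste(miss, collapse = ", "))
  ref <- stack$layers[[model$covariates[1]]]
  n_cell <- length(ref$values)
  design_stub <- list(covariates = model$covariates,
                      kind_tags = model$kind_tags, encoding = model$encoding)
  mean_v <- rep(NA_real_, n_cell)
  qv <- matrix(NA_real_, n_cell, length(levels))
  chunk <- 20000L
  for (st in seq(1L, n_cell, by = chunk)) {
    cells <- st:min(st + chunk - 1L, n_cell)
    X <- stack_design_rows(stack, design_stub, cells)
    pr <- predict(model, X, type = type, levels = levels)
    if (!is.null(pr$mean)) mean_v[cells] <- pr$mean
    if (!is.null(pr$quantiles)) qv[cells, ] <- pr$quantiles
  }
  mk <- function(v) raster_grid(matrix(v, nrow(ref$values), ncol(ref$values)),
                                cell_size = ref$cell_size, xll = ref$xll,
                                yll = ref$yll)
  list(mean = mk(mean_v),
       quantiles = lapply(seq_along(levels), function(i) mk(qv[, i])))
}

#' Predict the mean carbon-flux map
#'
#' Per-pixel prediction via the base learners and the meta learner;
#' missing covariates propagate to missing predictions.
#'
#' @param model a fitted `flux_ensemble`.
#' @param stack a [covariate_stack()] containing every retained covariate.
#' @return `raster_grid` of predicted flux (Mg C ha^-1).
#' @export
predict_flux <- function(model, stack) {
  predict_over_stack(model, stack, "mean")$mean
}

#' Predict flux quantile maps
#'
#' Empirical quantiles of the meta learner's leaf-pooled response
#' distribution at each pixel (quantile regression forest); the default
#' 5th/95th pair bounds a 90% prediction interval.
#'
#' @inheritParams predict_flux
#' @param levels two quantile levels in (0, 1).
#' @return list of two `raster_grid`s (`q05`, `q95` for the defaults).
#' @export
predict_quantiles <- function(model, stack, levels = c(0.05, 0.95)) {
  if (any(levels <= 0 | levels >= 1)) {
    stop("parameter error: quantile levels must be inside (0, 1)")
  }
  q <- predict_over_stack(model, stack, "quantiles", levels)$quantiles
  names(q) <- sprintf("q%02.0f", 100 * levels)
  q
}

#' Full ensemble prediction bundle
#'
#' Mean flux, the 5th/95th quantile maps, and the Gaussian-equivalent SD
#' layer derived from the 90% interval ([sd_from_interval()]).
#'
#' @inheritParams predict_flux
#' @param sd_mode passed to [sd_from_interval()].
#' @return object of class `ensemble_prediction` with `mean_flux`, `q05`,
#'   `q95`, `sd_flux`.
#' @export
predict_ensemble <- function(model, stack, sd_mode = "corrected") {
  pr <- predict_over_stack(model, stack, "both")
  q05 <- pr$quantiles[[1]]; q95 <- pr$quantiles[[2]]
  structure(list(mean_flux = pr$mean, q05 = q05, q95 = q95,
                 sd_flux = sd_from_interval(q05, q95, mode = sd_mode)),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat("ensemble_prediction: mean flux with 90% interval and SD layers\n")
  print(x$mean_flux)
  invisible(x)
}

# ---- importance ------------------------------------------------------------

#' Permutation importance of covariates
#'
#' For each base learner and cross-validation fold, each covariate is
#' permuted (one seeded shuffle; one-hot blocks of a categorical
#' covariate are shuffled jointly) in the held-out fold and the increase
#' in RMSE recorded, then averaged over folds. Per-learner scores are
#' combined with weights equal to the meta learner's own permutation
#' importance of each base-prediction column, and rescaled so the top
#' covariate scores 100.
#'
#' @param model a fitted `flux_ensemble` (retains its fold fits).
#' @param design the design matrix the model was fit on.
#' @return object of class `importance_table`: `per_covariate` (0-100),
#'   `per_base` matrix, `base_weights`.
#' @export
permutation_importance <- function(model, design) {
  if (is.null(model$fold_fits)) stop("state error: model has no fold fits")
  covs <- model$covariates
  k <- length(model$fold_fits)
  fam <- names(model$base_learners)
  per_base <- matrix(0, length(fam), length(covs),
                     dimnames = list(fam, covs))
  for (b in seq_along(fam)) {
    for (f in seq_len(k)) {
      hold <- model$fold_assignment == f
      Xf <- design$X[hold, , drop = FALSE]
      yf <- design$response[hold]
      p0 <- predict_one_learner(model$fold_fits[[f]][[b]], Xf)
      rmse0 <- sqrt(mean((yf - p0)^2))
      for (ci in seq_along(covs)) {
        blk <- grep(paste0("^", covs[ci], "($|\\.)"), colnames(Xf))
        Xp <- Xf
        perm <- with_seed(derive_seed(model$seed, 5000L + b * 97L + f * 13L + ci),
                          sample(nrow(Xf)))
        Xp[, blk] <- Xf[perm, blk, drop = FALSE]
        p1 <- predict_one_learner(model$fold_fits[[f]][[b]], Xp)
        per_base[b, ci] <- per_base[b, ci] +
          (sqrt(mean((yf - p1)^2)) - rmse0) / k
      }
    }
  }
  score <- drop(model$base_to_meta_importance %*% per_base)
  score <- pmax(score, 0)
  if (max(score) > 0) score <- 100 * score / max(score)
  structure(list(per_covariate = score, per_base = per_base,
                 base_weights = model$base_to_meta_importance),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  s <- sort(x$per_covariate, decreasing = TRUE)
  cat("permutation importance (0-100):\n")
  for (nm in names(s)) cat(sprintf("  %-20s %6.1f\n", nm, s[[nm]]))
  invisible(x)
}

#' Aggregate importance by covariate category
#'
#' Category shares are sums of covariate scores normalized to total 1.
#' Super-categories group the global above-ground-biomass products
#' (CCI, Flux, AGB, CONUS) against other dynamic inputs (environmental
#' dynamics, land cover) and static inputs (management, topography,
#' climate).
#'
#' @param table an [permutation_importance()] result.
#' @param category_tags named category per covariate.
#' @return list with `per_category` and `per_supercategory` shares.
#' @export
aggregate_importance <- function(table, category_tags) {
  covs <- names(table$per_covariate)
  miss <- setdiff(covs, names(category_tags))
  if (length(miss)) stop("untagged covariate: ", paste(miss, collapse = ", "))
  cats <- category_tags[covs]
  tot <- sum(table$per_covariate)
  if (tot == 0) stop("all importance scores are zero")
  pc <- tapply(table$per_covariate, cats, sum) / tot
  per_cat <- stats::setNames(as.numeric(pc), names(pc))
  super_of <- function(cat) {
    if (cat %in% c("CCI", "Flux", "AGB", "CONUS")) "global-AGB-maps"
    else if (cat %in% c("envi", "LC")) "other-dynamic"
    else "static"
  }
  sup <- vapply(names(per_cat), super_of, character(1))
  ps <- tapply(as.numeric(per_cat), sup, sum)
  per_super <- stats::setNames(as.numeric(ps), names(ps))
  for (lvl in c("global-AGB-maps", "other-dynamic", "static")) {
    if (!lvl %in% names(per_super)) per_super[lvl] <- 0
  }
  list(per_category = per_cat, per_supercategory = per_super)
}
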