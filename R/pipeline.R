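#' Default pipeline configuration
#'
#' Demonstration configuration on a 100 x 100 synthetic landscape: the
#' scenario block feeds [scenario_spec()], the remaining blocks
#' parameterize each pipeline stage. Learner grids are single
#' combinations sized for an interactive run; pass `full_grids = TRUE`
#' for the tuning grids used in model development.
#'
#' @param seed master seed; every stage seed derives from it.
#' @param full_grids use the full hyperparameter grids.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L, full_grids = FALSE) {
  list(
    seed = as.integer(seed),
    scenario = list(grid_shape = c(100L, 100L), n_plots = 400L),
    carbon_fraction = 0.49,
    variance_model = list(nfi_relative_sd = 0.2, floor = 1),
    glcm = list(window_cells = 3, gray_levels = 32),
    screening = list(n_sample = 5000, r_threshold = 0.8),
    coverage = list(k = 5),
    learners = if (full_grids) NULL else list(
      bagged_trees = list(num_trees = 250, mtry_frac = NA),
      gradient_boosted_trees = list(nrounds = 150, max_depth = 3, eta = 0.1),
      kernel_margin = list(cost = 1, bw_mult = 1)),
    cv = list(k = 5, enabled = TRUE),
    variogram = list(n_lags = 12, max_dist_m = NULL),
    aggregation = list(mode = "independent", eq4_mode = "corrected",
                       cell_area_ha = 1)
  )
}

# Build learner specs from a config learner block (NULL = default grids).
config_learner_specs <- function(block) {
  if (is.null(block)) return(default_learner_specs())
  mapply(function(fam, grid) learner_spec(fam, hyper_grid = lapply(grid, c)),
         names(block), block, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Run the full carbon-accounting pipeline
#'
#' Executes simulate, prepare, covariates, fit, evaluate, predict,
#' coverage, aggregate and account on a synthetic scenario, writing all
#' artifacts (plots CSV, retained-covariate list, correlation matrix,
#' metrics, importance, variogram, coverage and account CSVs, grid
#' layers as Esri ASCII, and a run manifest) to `out_dir`. Re-running
#' with an identical configuration reproduces identical numeric outputs.
#'
#' @param config nested list as from [default_config()], or the path to
#'   a YAML file holding one.
#' @param out_dir output directory (created if needed).
#' @param write_grids also write the large raster layers (off by default
#'   to keep runs light).
#' @return (invisibly) list with every stage result.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run"),
                         write_grids = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must define a master seed")
  config <- utils::modifyList(default_config(seed = config$seed), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  scn <- stage("simulate", {
    spec <- do.call(scenario_spec, c(config$scenario, list(seed = seed)))
    simulate_scenario(spec)
  })

  refset <- stage("prepare", {
    r <- filter_plots(scn$plots)
    if (r$units_note == "biomass") {
      r <- biomass_to_carbon(r, config$carbon_fraction)
    }
    r <- estimate_plot_variance(r, config$variance_model$nfi_relative_sd,
                                config$variance_model$floor)
    compute_case_weights(r)
  })
  write_plots_csv(refset, file.path(out_dir, "plots.csv"))

  stackres <- stage("covariates", {
    layers <- scn$covariates
    ncv <- length(layers)
    cats <- stats::setNames(
      c("CCI", "Flux", rep("envi", max(ncv - 2, 0)))[seq_len(ncv)],
      names(layers))
    tex <- compute_glcm_textures(layers[[1]],
                                 window_cells = config$glcm$window_cells,
                                 gray_levels = config$glcm$gray_levels)
    names(tex) <- paste0(names(tex), "_cci")
    layers <- c(layers, tex)
    cats[names(tex)] <- "CCI"
    layers$lcov10 <- scn$landcover_2010
    layers$lcov18 <- scn$landcover_2018
    cats[c("lcov10", "lcov18")] <- "LC"
    stack <- covariate_stack(layers, category_tags = cats)
    scr <- screen_collinearity(stack, n_sample = config$screening$n_sample,
                               r_threshold = config$screening$r_threshold,
                               always_keep = c("lcov10", "lcov18"),
                               seed = derive_seed(seed, 51L))
    list(stack = stack, screening = scr)
  })
  utils::write.csv(data.frame(retained = stackres$screening$retained),
                   file.path(out_dir, "retained_covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(stackres$screening$cor_matrix),
                   file.path(out_dir, "correlation_matrix.csv"))

  design <- stage("design", {
    extract_at_plots(stackres$stack, refset, stackres$screening$retained)
  })

  specs <- stage("tune", {
    lapply(config_learner_specs(config$learners), tune_base_learner,
           design = design, k = config$cv$k, seed = derive_seed(seed, 61L))
  })

  model <- stage("fit", {
    fit_stacked_ensemble(design, specs, k = config$cv$k,
                         seed = derive_seed(seed, 71L))
  })

  cv <- if (isTRUE(config$cv$enabled)) stage("evaluate", {
    cross_validate(design, specs, k = config$cv$k,
                   seed = derive_seed(seed, 81L))
  }) else NULL
  if (!is.null(cv)) {
    utils::write.csv(cv$per_fold, file.path(out_dir, "cv_folds.csv"),
                     row.names = FALSE)
    utils::write.csv(cv$summary, file.path(out_dir, "cv_summary.csv"),
                     row.names = FALSE)
  }

  imp <- stage("importance", {
    permutation_importance(model, design)
  })
  utils::write.csv(data.frame(covariate = names(imp$per_covariate),
                              importance = as.numeric(imp$per_covariate)),
                   file.path(out_dir, "importance.csv"), row.names = FALSE)

  pred <- stage("predict", {
    predict_ensemble(model, stackres$stack,
                     sd_mode = config$aggregation$eq4_mode)
  })

  classmap <- stage("reclassify", {
    reclassify_landcover(scn$landcover_2018, scn$plantation_mask,
                         target_cell_m = scn$spec$cell_size_m)
  })

  coverage <- stage("coverage", {
    cont <- imp$per_covariate[
      names(imp$per_covariate) %in%
        design$covariates[design$kind_tags[design$covariates] == "continuous"]]
    di <- compute_dissimilarity(stackres$stack, design, cont)
    thr <- coverage_threshold(design, cont, k = config$coverage$k,
                              seed = derive_seed(seed, 91L))
    undersampled_report(di, thr, classmap)
  })
  utils::write.csv(data.frame(
    unseea_class = c(names(coverage$fraction_by_class), "total"),
    fraction_undersampled = c(as.numeric(coverage$fraction_by_class),
                              coverage$fraction_total)),
    file.path(out_dir, "coverage.csv"), row.names = FALSE)

  agg <- stage("aggregate", {
    res <- standardized_residuals(pred, refset)
    emp <- empirical_variogram(res, n_lags = config$variogram$n_lags,
                               max_dist_m = config$variogram$max_dist_m)
    cg <- fit_correlogram(emp)
    mode <- config$aggregation$mode
    labs <- classmap$levels
    variances <- list()
    for (cd in seq_along(labs)) {
      msk <- classmap$values == cd & !is.na(classmap$values)
      if (!any(msk)) next
      variances[[labs[cd]]] <- list(
        flux = aggregate_class_variance(
          pred$sd_flux, msk, cg, config$aggregation$cell_area_ha,
          mode = mode, unseea_class = labs[cd]),
        opening = aggregate_class_variance(
          scn$opening_sd, msk, cg, config$aggregation$cell_area_ha,
          mode = mode, unseea_class = labs[cd]))
    }
    list(residuals = res, variogram = emp, correlogram = cg,
         variances = variances)
  })
  utils::write.csv(agg$variogram, file.path(out_dir, "variogram.csv"),
                   row.names = FALSE)

  account <- stage("account", {
    tot <- class_totals(scn$opening_stock, pred$mean_flux, classmap,
                        cell_area_ha = config$aggregation$cell_area_ha)
    spl <- emissions_split(pred$mean_flux, classmap, scn$landcover_2010,
                           scn$landcover_2018,
                           cell_area_ha = config$aggregation$cell_area_ha)
    build_account_table(tot, agg$variances, spl)
  })
  write_account_csv(account, file.path(out_dir, "account.csv"))

  if (write_grids) {
    write_ascii_grid(pred$mean_flux, file.path(out_dir, "flux_mean.asc"))
    write_ascii_grid(pred$q05, file.path(out_dir, "flux_q05.asc"))
    write_ascii_grid(pred$q95, file.path(out_dir, "flux_q95.asc"))
    write_ascii_grid(coverage$dissimilarity, file.path(out_dir, "di.asc"))
  }

  yaml::write_yaml(list(
    package = "seeaflux",
    version = as.character(utils::packageVersion("seeaflux")),
    seed = seed,
    config = config,
    n_plots_used = nrow(design$X),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  ), file.path(out_dir, "run_manifest.yaml"))

  invisible(list(scenario = scn, refset = refset, stack = stackres$stack,
                 screening = stackres$screening, design = design,
                 specs = specs, model = model, cv = cv, importance = imp,
                 prediction = pred, classmap = classmap, coverage = coverage,
                 aggregation = agg, account = account, out_dir = out_dir))
}
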