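#' Scenario specification for synthetic landscapes
#'
#' Defines the statistical conditions under which the pipeline is
#' exercised: spatially autocorrelated standardized covariate fields, a
#' true net carbon-flux surface that is a known linear function of the
#' covariates plus (optionally spatially correlated) Gaussian noise, a
#' land-cover pair with forest-to-non-forest transitions, a plantation
#' mask nested in forest, an opening carbon-stock layer with a relative-SD
#' uncertainty layer, and plot samples with heteroscedastic measurement
#' error under uniform, systematic or clustered designs.
#'
#' Default conditions: a 100 x 100 grid of 100 m cells, six standardized
#' covariate fields with 1000 m correlation length, flux coefficients
#' (8, -6, 4, -2, 1, 0) giving a signal SD of about 11 Mg C ha^-1, and
#' residual noise SD 5.5 Mg C ha^-1 — a 2:1 signal-to-noise ratio typical
#' of the regional flux-mapping problems the method targets.
#'
#' @param grid_shape integer (rows, cols).
#' @param cell_size_m cell edge, m.
#' @param n_covariates number of continuous covariate fields.
#' @param covariate_corr_length_m correlation length of the covariate
#'   fields (Gaussian-kernel SD of the smoother), m; 0 gives white noise.
#' @param flux_coefficients one coefficient per covariate (Mg C ha^-1 per
#'   SD of the covariate).
#' @param noise_sd residual noise SD, Mg C ha^-1.
#' @param noise_corr_length_m correlation length of the noise field; 0
#'   gives independent pixel noise.
#' @param landcover_classes UNSEEA class labels for the 2010 map; classes
#'   listed in [forest_classes()] count as forest.
#' @param transition_fraction share of 2010 forest pixels reassigned to
#'   the first non-forest label in 2018.
#' @param plantation_fraction share of forest pixels flagged plantation.
#' @param sampling_design "uniform", "systematic" or "clustered".
#' @param n_plots number of reference plots.
#' @param cluster_count,cluster_radius_m clustered-design geometry.
#' @param measurement_cv relative SD of the plot flux measurement; the
#'   absolute SD is `measurement_cv * max(|flux|, 1)` so that plot
#'   variances (and hence inverse-variance weights) are defined even at
#'   zero flux.
#' @param opening_mean,opening_rel_sd mean opening stock (Mg C ha^-1) and
#'   the relative SD of its per-pixel uncertainty layer.
#' @param seed integer master seed for the scenario.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(grid_shape = c(100L, 100L),
                          cell_size_m = 100,
                          n_covariates = 6L,
                          covariate_corr_length_m = 1000,
                          flux_coefficients = c(8, -6, 4, -2, 1, 0)[seq_len(n_covariates)],
                          noise_sd = 5.5,
                          noise_corr_length_m = 0,
                          landcover_classes = c("broadleaved", "coniferous",
                                                "mixed", "other_woody"),
                          transition_fraction = 0.1,
                          plantation_fraction = 0.1,
                          sampling_design = c("uniform", "systematic", "clustered"),
                          n_plots = 500L,
                          cluster_count = 10L,
                          cluster_radius_m = 500,
                          measurement_cv = 0.1,
                          opening_mean = 100,
                          opening_rel_sd = 0.2,
                          seed = 1L) {
  sampling_design <- match.arg(sampling_design)
  if (any(grid_shape < 1)) stop("grid_shape must be positive")
  if (cell_size_m <= 0) stop("cell_size_m must be positive")
  if (covariate_corr_length_m < 0) {
    stop("parameter error: covariate correlation length must be >= 0")
  }
  if (transition_fraction < 0 || transition_fraction > 1) {
    stop("transition_fraction must be in [0, 1]")
  }
  if (n_plots > prod(grid_shape)) {
    stop("parameter error: n_plots exceeds the number of grid cells")
  }
  if (length(flux_coefficients) != n_covariates) {
    stop("flux_coefficients must have one entry per covariate")
  }
  if (noise_sd < 0 || noise_corr_length_m < 0 || measurement_cv < 0) {
    stop("noise and measurement parameters must be >= 0")
  }
  structure(list(
    grid_shape = as.integer(grid_shape), cell_size_m = cell_size_m,
    n_covariates = as.integer(n_covariates),
    covariate_corr_length_m = covariate_corr_length_m,
    flux_coefficients = flux_coefficients, noise_sd = noise_sd,
    noise_corr_length_m = noise_corr_length_m,
    landcover_classes = landcover_classes,
    transition_fraction = transition_fraction,
    plantation_fraction = plantation_fraction,
    sampling_design = sampling_design, n_plots = as.integer(n_plots),
    cluster_count = as.integer(cluster_count),
    cluster_radius_m = cluster_radius_m,
    measurement_cv = measurement_cv, opening_mean = opening_mean,
    opening_rel_sd = opening_rel_sd, seed = as.integer(seed)
  ), class = "scenario_spec")
}

#' UNSEEA labels treated as forest
#'
#' @return character vector of the class labels counted as forest when
#'   land-cover transitions and emission attribution are computed.
#' @export
forest_classes <- function() {
  c("broadleaved", "coniferous", "mixed", "mangroves", "plantation")
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a stage seed from a master seed; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + k) %% 2147483647)
}

# Stationary Gaussian random field: Gaussian-kernel smoothing of white
# noise, re-standardized to mean 0 / SD 1. `sd_cells` is the kernel SD in
# cell units and plays the role of the correlation length.
gaussian_field <- function(nr, nc, sd_cells) {
  if (sd_cells <= 0) {
    f <- matrix(stats::rnorm(nr * nc), nr, nc)
  } else {
    p <- ceiling(3 * sd_cells)
    k <- stats::dnorm(seq(-p, p), sd = sd_cells)
    k <- k / sum(k)
    noise <- matrix(stats::rnorm((nr + 2 * p) * (nc + 2 * p)),
                    nr + 2 * p, nc + 2 * p)
    wr <- matrix(0, nr, nr + 2 * p)
    for (i in seq_len(nr)) wr[i, i:(i + 2 * p)] <- k
    wc <- matrix(0, nc, nc + 2 * p)
    for (j in seq_len(nc)) wc[j, j:(j + 2 * p)] <- k
    f <- wr %*% noise %*% t(wc)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Generate standardized covariate random fields
#'
#' Draws `n_covariates` stationary random fields with the requested
#' correlation length, each standardized to mean 0 / SD 1. Deterministic
#' given the scenario seed.
#'
#' @param spec a [scenario_spec()].
#' @return named list of `raster_grid` layers (`cov1`, `cov2`, ...).
#' @export
generate_covariate_fields <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  s <- spec$covariate_corr_length_m / spec$cell_size_m
  with_seed(derive_seed(spec$seed, 1L), {
    out <- lapply(seq_len(spec$n_covariates), function(k) {
      raster_grid(gaussian_field(nr, nc, s), cell_size = spec$cell_size_m)
    })
    names(out) <- paste0("cov", seq_len(spec$n_covariates))
    out
  })
}

#' Generate the true net carbon-flux surface
#'
#' flux = sum of coefficient-weighted covariates plus Gaussian noise of
#' SD `noise_sd` (spatially correlated when `noise_corr_length_m > 0`).
#' Signed, Mg C ha^-1: losses negative, sequestration positive.
#'
#' @param covariates named list of aligned `raster_grid` covariates.
#' @param spec a [scenario_spec()].
#' @return `raster_grid` of true flux.
#' @export
generate_true_flux <- function(covariates, spec) {
  if (length(covariates) != length(spec$flux_coefficients)) {
    stop("dimension error: one coefficient per covariate is required")
  }
  do.call(check_aligned, covariates)
  ref <- covariates[[1]]
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  lin <- matrix(0, nr, nc)
  for (k in seq_along(covariates)) {
    lin <- lin + spec$flux_coefficients[k] * covariates[[k]]$values
  }
  if (spec$noise_sd > 0) {
    s <- spec$noise_corr_length_m / spec$cell_size_m
    noise <- with_seed(derive_seed(spec$seed, 2L),
                       gaussian_field(nr, nc, s)) * spec$noise_sd
    lin <- lin + noise
  }
  raster_grid(lin, cell_size = ref$cell_size, xll = ref$xll, yll = ref$yll)
}

#' Generate the 2010/2018 land-cover pair and plantation mask
#'
#' The 2010 map partitions pixels among the configured UNSEEA classes by
#' equal-quantile thresholds of a latent field. The 2018 map equals the
#' 2010 map except that `transition_fraction` of the forest pixels are
#' reassigned to the first non-forest label (forest conversion). The
#' plantation mask is a subset of the 2010 forest pixels.
#'
#' @param spec a [scenario_spec()].
#' @param latent `raster_grid` latent field aligned with the grid.
#' @return list with `landcover_2010`, `landcover_2018` (categorical
#'   `raster_grid`s) and `plantation_mask` (logical-valued `raster_grid`).
#' @export
generate_landcover_pair <- function(spec, latent) {
  classes <- spec$landcover_classes
  v <- latent$values
  qs <- stats::quantile(v, probs = seq(0, 1, length.out = length(classes) + 1))
  code <- matrix(findInterval(v, qs[-c(1, length(qs))]) + 1L,
                 nrow(v), ncol(v))
  lc10 <- raster_grid(code, cell_size = latent$cell_size, xll = latent$xll,
                      yll = latent$yll, levels = classes)
  is_forest <- matrix(classes[code] %in% forest_classes(), nrow(v), ncol(v))
  forest_idx <- which(is_forest)
  code18 <- code
  if (spec$transition_fraction > 0) {
    nonforest <- which(!(classes %in% forest_classes()))
    if (!length(nonforest)) {
      stop("parameter error: no non-forest class available for transitions")
    }
    if (!length(forest_idx)) {
      stop("parameter error: no forest pixels available for transitions")
    }
    n_flip <- round(spec$transition_fraction * length(forest_idx))
    flip <- with_seed(derive_seed(spec$seed, 3L),
                      sample(forest_idx, n_flip))
    code18[flip] <- nonforest[1]
  }
  lc18 <- raster_grid(code18, cell_size = latent$cell_size, xll = latent$xll,
                      yll = latent$yll, levels = classes)
  # plantation: highest-latent share of forest pixels
  plant <- matrix(FALSE, nrow(v), ncol(v))
  if (spec$plantation_fraction > 0 && length(forest_idx)) {
    n_pl <- round(spec$plantation_fraction * length(forest_idx))
    ord <- forest_idx[order(v[forest_idx], decreasing = TRUE)]
    plant[ord[seq_len(n_pl)]] <- TRUE
  }
  pm <- raster_grid(plant + 0, cell_size = latent$cell_size,
                    xll = latent$xll, yll = latent$yll)
  list(landcover_2010 = lc10, landcover_2018 = lc18, plantation_mask = pm)
}

#' Sample reference plots from the true flux surface
#'
#' Observed flux at each plot is the true flux at its cell plus Gaussian
#' measurement error with SD `measurement_cv * max(|true flux|, 1)`; the
#' corresponding variance is recorded per plot. Plots are placed at cell
#' centres under the requested design.
#'
#' @param true_flux `raster_grid` of the true flux.
#' @param spec a [scenario_spec()].
#' @return a [reference_set()] with `units_note = "carbon"`.
#' @export
sample_plots <- function(true_flux, spec) {
  nr <- nrow(true_flux$values); nc <- ncol(true_flux$values)
  if (spec$n_plots > nr * nc) stop("parameter error: n_plots exceeds grid")
  idx <- with_seed(derive_seed(spec$seed, 4L), switch(
    spec$sampling_design,
    uniform = {
      cells <- sample(nr * nc, spec$n_plots)
      cbind(row = (cells - 1L) %% nr + 1L, col = (cells - 1L) %/% nr + 1L)
    },
    systematic = {
      sx <- sqrt(nr * nc / spec$n_plots)
      rows <- round(seq(sx / 2 + 0.5, nr, by = sx))
      cols <- round(seq(sx / 2 + 0.5, nc, by = sx))
      rows <- rows[rows >= 1 & rows <= nr]
      cols <- cols[cols >= 1 & cols <= nc]
      as.matrix(expand.grid(row = rows, col = cols))
    },
    clustered = {
      ctr <- cbind(runif(spec$cluster_count, 0.5, nr + 0.5),
                   runif(spec$cluster_count, 0.5, nc + 0.5))
      rad <- spec$cluster_radius_m / spec$cell_size_m
      out <- matrix(NA_integer_, spec$n_plots, 2)
      for (i in seq_len(spec$n_plots)) {
        c_i <- ((i - 1L) %% spec$cluster_count) + 1L
        repeat {
          a <- runif(1, 0, 2 * pi); r <- rad * sqrt(runif(1))
          rr <- round(ctr[c_i, 1] + r * sin(a))
          cc <- round(ctr[c_i, 2] + r * cos(a))
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
            out[i, ] <- c(rr, cc); break
          }
        }
      }
      colnames(out) <- c("row", "col")
      out
    }))
  n <- nrow(idx)
  ctr <- grid_centres(true_flux)
  truth <- true_flux$values[idx]
  sd_i <- spec$measurement_cv * pmax(abs(truth), 1)
  obs <- truth + with_seed(derive_seed(spec$seed, 5L), stats::rnorm(n)) * sd_i
  reference_set(data.frame(
    plot_id = sprintf("P%05d", seq_len(n)),
    x = ctr$x[idx[, "col"]],
    y = ctr$y[idx[, "row"]],
    flux_obs = obs,
    flux_var = sd_i^2,
    source = "NFI",
    forest_change_flag = FALSE,
    edge_flag = FALSE,
    stringsAsFactors = FALSE
  ), design_tag = spec$sampling_design, units_note = "carbon")
}

#' Simulate a complete synthetic scenario
#'
#' Bundles covariates, true flux, the land-cover pair, plantation mask,
#' opening-stock and opening-SD layers, and a plot sample, together with a
#' truth record sufficient to reconstruct the noise-free flux from the
#' covariates. Bit-identical under an identical spec (including seed).
#'
#' @param spec a [scenario_spec()].
#' @return object of class `synthetic_scenario`.
#' @export
simulate_scenario <- function(spec) {
  covs <- generate_covariate_fields(spec)
  flux <- generate_true_flux(covs, spec)
  latent <- raster_grid(with_seed(derive_seed(spec$seed, 6L),
                                  gaussian_field(spec$grid_shape[1],
                                                 spec$grid_shape[2],
                                                 spec$covariate_corr_length_m /
                                                   spec$cell_size_m)),
                        cell_size = spec$cell_size_m)
  lc <- generate_landcover_pair(spec, latent)
  plots <- sample_plots(flux, spec)
  opening <- raster_grid(
    pmax(spec$opening_mean + 25 * covs[[1]]$values +
           10 * covs[[min(2, length(covs))]]$values, 5),
    cell_size = spec$cell_size_m)
  opening_sd <- raster_grid(spec$opening_rel_sd * opening$values,
                            cell_size = spec$cell_size_m)
  structure(list(
    covariates = covs, true_flux = flux,
    landcover_2010 = lc$landcover_2010, landcover_2018 = lc$landcover_2018,
    plantation_mask = lc$plantation_mask,
    opening_stock = opening, opening_sd = opening_sd,
    plots = plots,
    truth_record = list(flux_coefficients = spec$flux_coefficients,
                        noise_sd = spec$noise_sd,
                        noise_corr_length_m = spec$noise_corr_length_m,
                        seed = spec$seed),
    spec = spec
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic_scenario: %d x %d grid (%g m), %d covariates, %d plots (%s)\n",
    x$spec$grid_shape[1], x$spec$grid_shape[2], x$spec$cell_size_m,
    length(x$covariates), nrow(x$plots$records), x$spec$sampling_design))
  invisible(x)
}
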