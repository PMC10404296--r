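#' Standard-deviation layer from a 90% prediction interval
#'
#' Converts the 5th/95th quantile maps into a per-pixel SD layer. The
#' default corrected mode uses the Gaussian identity for a 90% interval,
#' SD = (q95 - q05) / (2 x 1.645); the literal mode reproduces the form
#' SD = ((q95 - q05) / 2) x 1.64, which multiplies rather than divides
#' the half-width by the normal quantile and therefore inflates the SD by
#' about 2.7x. Both modes are kept because published accounts have used
#' the literal form; the mode is recorded on the result.
#'
#' @param q05,q95 aligned quantile `raster_grid`s with q05 <= q95.
#' @param mode `"corrected"` or `"literal"`.
#' @return `raster_grid` of SDs with attribute `mode`.
#' @export
sd_from_interval <- function(q05, q95, mode = c("corrected", "literal")) {
  mode <- match.arg(mode)
  check_aligned(q05, q95)
  bad <- which(q05$values > q95$values + 1e-12)
  if (length(bad)) {
    stop(sprintf("q05 > q95 at pixel %d (row %d, col %d)", bad[1],
                 (bad[1] - 1) %% nrow(q05$values) + 1,
                 (bad[1] - 1) %/% nrow(q05$values) + 1))
  }
  width <- q95$values - q05$values
  sd <- if (mode == "corrected") width / (2 * 1.645)
        else (width / 2) * 1.64
  out <- raster_grid(sd, cell_size = q05$cell_size, xll = q05$xll,
                     yll = q05$yll)
  attr(out, "mode") <- mode
  out
}

#' Standardized map residuals at plot locations
#'
#' r(s) = (z(s) - zhat(s)) / SD(s) at each retained plot's cell, using
#' the prediction's mean and SD layers. Plots falling on missing
#' prediction cells are dropped with a message. When the SD layer is well
#' calibrated the residuals have unit variance.
#'
#' @param prediction an [predict_ensemble()] result (or any list with
#'   `mean_flux` and `sd_flux` grids).
#' @param refset a [reference_set()].
#' @return data.frame with `x`, `y`, `residual`.
#' @export
standardized_residuals <- function(prediction, refset) {
  rec <- refset$records
  zhat <- extract_cells(prediction$mean_flux, rec$x, rec$y)
  sd <- extract_cells(prediction$sd_flux, rec$x, rec$y)
  ok <- is.finite(zhat) & is.finite(sd) & sd > 0
  if (any(!ok)) {
    message(sprintf("standardized_residuals: dropped %d plots on missing or zero-SD cells",
                    sum(!ok)))
  }
  data.frame(x = rec$x[ok], y = rec$y[ok],
             residual = (rec$flux_obs[ok] - zhat[ok]) / sd[ok])
}

#' Empirical variogram (Matheron estimator)
#'
#' gamma(h) = (1 / 2N(h)) sum over pairs of (r_i - r_j)^2, with pairs
#' binned into equal-width distance classes; zero-distance pairs are
#' excluded. Empty bins are omitted.
#'
#' @param points data.frame with `x`, `y`, `residual`.
#' @param n_lags number of distance bins.
#' @param max_dist_m maximum pair separation; defaults to half the
#'   bounding-box diagonal.
#' @return data.frame `lag` (bin midpoint, m), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(points, n_lags = 15, max_dist_m = NULL) {
  if (nrow(points) < 4) stop("need at least 4 points for a variogram")
  if (nrow(points) < 30) {
    warning("fewer than 30 points; the empirical variogram will be unstable")
  }
  d <- stats::dist(points[, c("x", "y")])
  if (is.null(max_dist_m)) {
    max_dist_m <- sqrt(diff(range(points$x))^2 + diff(range(points$y))^2) / 2
  }
  g <- stats::dist(points$residual)^2 / 2
  keep <- d > 0 & d <= max_dist_m
  dv <- d[keep]; gv <- g[keep]
  brk <- seq(0, max_dist_m, length.out = n_lags + 1)
  bin <- findInterval(dv, brk, rightmost.closed = TRUE, all.inside = TRUE)
  out <- data.frame(
    lag = (brk[-1] + brk[-length(brk)]) / 2,
    gamma = as.numeric(tapply(gv, factor(bin, levels = seq_len(n_lags)), mean)),
    n_pairs = as.integer(table(factor(bin, levels = seq_len(n_lags))))
  )
  out[out$n_pairs > 0, , drop = FALSE]
}

#' Fit a correlogram model to an empirical variogram
#'
#' Fits nugget, partial sill and range by pair-count-weighted least
#' squares. The exponential family gamma(h) = nugget +
#' psill (1 - exp(-h / range)) is the default; its effective range
#' (95% decorrelation) is 3x the range parameter. On non-convergence the
#' model falls back to pure nugget (no spatial correlation) with a
#' warning. The derived correlation function is
#' rho(h) = psill exp(-h / range) / (nugget + psill) for h > 0 and
#' rho(0) = 1, truncated to 0 beyond the effective range.
#'
#' @param emp data.frame from [empirical_variogram()].
#' @param family `"exponential"` or `"spherical"`.
#' @return object of class `correlogram_model`: `family`, `nugget`,
#'   `partial_sill`, `range_m` (range parameter), `effective_range_m`,
#'   `empirical_lags`, `converged`.
#' @export
fit_correlogram <- function(emp, family = c("exponential", "spherical")) {
  family <- match.arg(family)
  if (nrow(emp) < 4) stop("need at least 4 non-empty bins")
  sill0 <- mean(emp$gamma[emp$lag > stats::median(emp$lag)])
  nug0 <- max(min(emp$gamma), 1e-6)
  # the nugget/sill split below the first lag is unidentifiable, so the
  # range parameter is bounded below by the first lag midpoint
  rmin <- max(min(emp$lag), 1e-6)
  rng0 <- max(stats::median(emp$lag) / 3, rmin)
  model_fun <- if (family == "exponential") {
    function(h, n, p, r) n + p * (1 - exp(-h / r))
  } else {
    function(h, n, p, r) {
      ifelse(h < r, n + p * (1.5 * h / r - 0.5 * (h / r)^3), n + p)
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      gamma ~ model_fun(lag, n, p, r),
      data = emp,
      start = list(n = nug0, p = max(sill0 - nug0, 1e-6), r = rng0),
      lower = c(0, 0, rmin), weights = emp$n_pairs,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  nug_flat <- stats::weighted.mean(emp$gamma, emp$n_pairs)
  sse_flat <- sum(emp$n_pairs * (emp$gamma - nug_flat)^2)
  if (is.null(fit)) {
    warning("variogram fit did not converge; falling back to a pure-nugget model")
    co <- c(n = nug_flat, p = 0, r = 1)
    conv <- FALSE
  } else {
    co <- stats::coef(fit)
    conv <- TRUE
    # parsimony: nugget and sill are not identifiable from a flat
    # variogram, so the structured model (2 extra parameters) is kept
    # only when it improves significantly on the pure-nugget fit
    # (F-test at the 5% level on the weighted residual sums of squares)
    sse_fit <- sum(emp$n_pairs *
                     (emp$gamma - model_fun(emp$lag, co["n"], co["p"],
                                            co["r"]))^2)
    df2 <- nrow(emp) - 3
    if (sse_flat > 0 && df2 > 0) {
      f_stat <- ((sse_flat - sse_fit) / 2) / (sse_fit / df2)
      if (f_stat < stats::qf(0.95, 2, df2)) {
        co <- c(n = nug_flat, p = 0, r = 1)
      }
    }
  }
  structure(list(
    family = family, nugget = unname(co["n"]),
    partial_sill = unname(co["p"]), range_m = unname(co["r"]),
    effective_range_m = if (family == "exponential") 3 * unname(co["r"])
                        else unname(co["r"]),
    empirical_lags = emp, converged = conv
  ), class = "correlogram_model")
}

#' @export
print.correlogram_model <- function(x, ...) {
  cat(sprintf(
    "correlogram_model (%s): nugget %.3f, partial sill %.3f, total sill %.3f\n",
    x$family, x$nugget, x$partial_sill, x$nugget + x$partial_sill))
  cat(sprintf("  effective range %.0f m%s\n", x$effective_range_m,
              if (x$converged) "" else " (pure-nugget fallback)"))
  invisible(x)
}

#' Spatial correlation at distance h
#'
#' @param model a [fit_correlogram()] model.
#' @param h distances, m.
#' @return rho(h) in [0, 1]; 1 at h = 0, 0 beyond the effective range.
#' @export
correlogram_rho <- function(model, h) {
  sill <- model$nugget + model$partial_sill
  if (sill <= 0) return(ifelse(h == 0, 1, 0))
  rho <- if (model$family == "exponential") {
    model$partial_sill * exp(-h / model$range_m) / sill
  } else {
    hr <- pmin(h / model$range_m, 1)
    model$partial_sill * (1 - 1.5 * hr + 0.5 * hr^3) / sill
  }
  rho[h == 0] <- 1
  rho[h > model$effective_range_m] <- 0
  rho
}

#' Aggregate per-pixel SDs to a class variance
#'
#' Per-pixel SDs (Mg C ha^-1) are converted to per-pixel totals
#' (x cell area, ha) and summed over the class mask. Independent mode:
#' variance = sum SD_i^2 — the choice appropriate when residual spatial
#' correlation ranges are negligible at the aggregation scale.
#' Correlated mode: variance = sum_i sum_j rho(h_ij) SD_i SD_j with rho
#' from the correlogram (1 at h = 0, truncated beyond the effective
#' range); the truncation makes an exact local-window summation over
#' offset vectors feasible. Results are reported in Tg C
#' (1 Tg = 10^6 Mg).
#'
#' @param sd_layer `raster_grid` of per-pixel SD, Mg C ha^-1.
#' @param class_mask logical matrix (or 0/1 `raster_grid`) selecting the
#'   class pixels.
#' @param correlogram a [fit_correlogram()] model (correlated mode only).
#' @param cell_area_ha cell area in ha.
#' @param mode `"independent"` or `"correlated"`.
#' @param unseea_class label stored on the result.
#' @return object of class `class_variance`: `n_pixels`, `variance_TgC2`,
#'   `sd_TgC`, `mode`.
#' @export
aggregate_class_variance <- function(sd_layer, class_mask, correlogram = NULL,
                                     cell_area_ha = 1,
                                     mode = c("independent", "correlated"),
                                     unseea_class = NA_character_) {
  mode <- match.arg(mode)
  msk <- if (inherits(class_mask, "raster_grid")) class_mask$values else class_mask
  msk <- msk > 0 & !is.na(msk)
  sd_mg <- sd_layer$values * cell_area_ha     # Mg C per pixel
  sd_mg[!msk | !is.finite(sd_mg)] <- 0
  if (mode == "independent") {
    var_mg2 <- sum(sd_mg^2)
  } else {
    if (is.null(correlogram)) {
      stop("parameter error: correlated mode requires a correlogram")
    }
    cs <- sd_layer$cell_size
    nr <- nrow(sd_mg); nc <- ncol(sd_mg)
    kmax <- min(floor(correlogram$effective_range_m / cs),
                max(nr, nc) - 1L)
    var_mg2 <- sum(sd_mg^2)                   # h = 0 term, rho = 1
    for (dr in 0:kmax) {
      for (dc in (-kmax):kmax) {
        if (dr == 0 && dc <= 0) next          # each offset pair once
        if (dr > nr - 1 || abs(dc) > nc - 1) next
        h <- cs * sqrt(dr^2 + dc^2)
        rho <- correlogram_rho(correlogram, h)
        if (rho <= 0) next
        r1 <- 1:(nr - dr); r2 <- (1 + dr):nr
        if (dc >= 0) { c1 <- 1:(nc - dc); c2 <- (1 + dc):nc }
        else { c1 <- (1 - dc):nc; c2 <- 1:(nc + dc) }
        s <- sum(sd_mg[r1, c1, drop = FALSE] * sd_mg[r2, c2, drop = FALSE])
        var_mg2 <- var_mg2 + 2 * rho * s
      }
    }
  }
  structure(list(unseea_class = unseea_class, n_pixels = sum(msk),
                 variance_TgC2 = var_mg2 / 1e12, sd_TgC = sqrt(var_mg2) / 1e6,
                 mode = mode),
            class = "class_variance")
}

#' @export
print.class_variance <- function(x, ...) {
  cat(sprintf("class_variance [%s]: %d pixels, SD %.4g Tg C (%s mode)\n",
              x$unseea_class, x$n_pixels, x$sd_TgC, x$mode))
  invisible(x)
}

#' Closing-stock variance
#'
#' Adds the aggregated opening-stock and flux variances assuming the two
#' error sources are independent; the SD is the square root of the sum.
#'
#' @param opening,flux `class_variance` objects for the same class and
#'   mode.
#' @return a `class_variance` for the closing stock.
#' @export
closing_stock_variance <- function(opening, flux) {
  if (!identical(opening$unseea_class, flux$unseea_class)) {
    stop("class mismatch between opening and flux variances")
  }
  if (!identical(opening$mode, flux$mode)) {
    stop("aggregation modes differ between opening and flux variances")
  }
  v <- opening$variance_TgC2 + flux$variance_TgC2
  structure(list(unseea_class = opening$unseea_class,
                 n_pixels = opening$n_pixels,
                 variance_TgC2 = v, sd_TgC = sqrt(v), mode = opening$mode),
            class = "class_variance")
}
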