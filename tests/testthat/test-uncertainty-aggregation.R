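test_that("interval-to-SD conversion implements both modes", {
  q05 <- raster_grid(matrix(-10, 2, 2))
  q95 <- raster_grid(matrix(10, 2, 2))
  sd_c <- sd_from_interval(q05, q95, mode = "corrected")
  expect_equal(sd_c$values[1, 1], 20 / 3.29, tolerance = 1e-6)
  expect_equal(attr(sd_c, "mode"), "corrected")
  sd_l <- sd_from_interval(q05, q95, mode = "literal")
  expect_equal(sd_l$values[1, 1], 16.4)
  # zero-width interval
  z <- sd_from_interval(q95, q95)
  expect_true(all(z$values == 0))
  # q05 > q95 rejected with pixel identification
  bad05 <- raster_grid(matrix(c(-10, 30, -10, -10), 2, 2))
  expect_error(sd_from_interval(bad05, q95), "pixel 2")
})

test_that("standardized residuals are exact at plots and calibrated on average", {
  v <- matrix(seq(-20, 20, length.out = 25), 5, 5)
  pred <- list(mean_flux = raster_grid(v),
               sd_flux = raster_grid(matrix(2, 5, 5)))
  rec <- data.frame(plot_id = c("a", "b"), x = c(50, 150), y = c(450, 450),
                    flux_obs = c(v[1, 1], v[1, 2] + 2), flux_var = 1,
                    source = "NFI", forest_change_flag = FALSE,
                    edge_flag = FALSE)
  rs <- reference_set(rec, "uniform", "carbon")
  res <- standardized_residuals(pred, rs)
  expect_equal(res$residual, c(0, 1))

  # calibration: residual SD near 1 when the SD layer is correct
  set.seed(6)
  n <- 400
  truth <- rnorm(n, sd = 8)
  sd_true <- 3
  obs <- truth + rnorm(n, sd = sd_true)
  g <- raster_grid(matrix(truth, 20, 20))
  predg <- list(mean_flux = g,
                sd_flux = raster_grid(matrix(sd_true, 20, 20)))
  ctr <- expand.grid(col = 1:20, row = 1:20)
  recs <- reference_set(data.frame(
    plot_id = as.character(1:n), x = (ctr$col - 0.5) * 100,
    y = (20 - ctr$row + 0.5) * 100,
    flux_obs = obs[(ctr$col - 1) * 20 + ctr$row], flux_var = 1,
    source = "NFI", forest_change_flag = FALSE, edge_flag = FALSE),
    "uniform", "carbon")
  resg <- standardized_residuals(predg, recs)
  expect_gt(sd(resg$residual), 0.8)
  expect_lt(sd(resg$residual), 1.2)
})

test_that("empirical variogram matches hand counts and white-noise level", {
  # 4 collinear points with residuals (0,1,0,1) at unit (100 m) spacing:
  # lag-100 pairs (0,1),(1,0),(0,1) -> gamma = 0.5
  pts <- data.frame(x = c(100, 200, 300, 400), y = 0,
                    residual = c(0, 1, 0, 1))
  # bins of width 50 m isolate the three distinct separation distances
  emp <- suppressWarnings(
    empirical_variogram(pts, n_lags = 7, max_dist_m = 350))
  expect_equal(nrow(emp), 3)              # empty bins omitted
  expect_equal(emp$n_pairs, c(3L, 2L, 1L))
  expect_equal(emp$gamma[1], 0.5)         # pairs (0,1),(1,0),(0,1)
  expect_equal(emp$gamma[2], 0)           # pairs (0,0),(1,1)
  expect_equal(emp$gamma[3], 0.5)         # pair (0,1)

  # spatially independent unit-variance residuals: gamma ~ 1 at all lags
  set.seed(12)
  wn <- data.frame(x = runif(400, 0, 5000), y = runif(400, 0, 5000),
                   residual = rnorm(400))
  ew <- empirical_variogram(wn, n_lags = 10, max_dist_m = 2500)
  se <- 1 / sqrt(ew$n_pairs)      # approximate standard error
  expect_true(all(abs(ew$gamma - 1) < 3 * pmax(se, 0.05)))
})

test_that("correlogram fitting recovers simulated parameters", {
  fits <- lapply(1:10, function(s) {
    pts <- sim_exp_field(400, 10000, eff_range_m = 2000, psill = 0.8,
                         nugget = 0.2, seed = s + 50)
    fit_correlogram(empirical_variogram(pts, n_lags = 15, max_dist_m = 5000))
  })
  eff <- vapply(fits, `[[`, numeric(1), "effective_range_m")
  sill <- vapply(fits, function(f) f$nugget + f$partial_sill, numeric(1))
  expect_lt(abs(median(eff) - 2000) / 2000, 0.25)
  expect_lt(abs(median(sill) - 1) / 1, 0.15)

  # white noise: near-pure nugget (median of 5 seeds; an individual draw
  # can show a spurious short-range dip)
  shares <- vapply(1:5, function(s) {
    set.seed(70 + s)
    wn <- data.frame(x = runif(400, 0, 5000), y = runif(400, 0, 5000),
                     residual = rnorm(400))
    fw <- suppressWarnings(
      fit_correlogram(empirical_variogram(wn, n_lags = 12,
                                          max_dist_m = 2500)))
    fw$partial_sill / (fw$nugget + fw$partial_sill)
  }, numeric(1))
  expect_lt(median(shares), 0.2)

  # fitted semivariance curve is non-decreasing in distance
  f1 <- fits[[1]]
  h <- seq(0, 6000, by = 100)
  gam <- f1$nugget + f1$partial_sill * (1 - exp(-h / f1$range_m))
  expect_true(all(diff(gam) >= -1e-12))
  # rho is 1 at the origin and zero beyond the effective range
  expect_equal(correlogram_rho(f1, 0), 1)
  expect_equal(correlogram_rho(f1, f1$effective_range_m * 1.01), 0)
})

test_that("windowed class-variance aggregation equals the double-loop oracle", {
  set.seed(13)
  cg <- structure(list(family = "exponential", nugget = 0.2,
                       partial_sill = 0.8, range_m = 300,
                       effective_range_m = 900, converged = TRUE),
                  class = "correlogram_model")
  for (rep in 1:3) {
    nr <- 15; nc <- 15
    sdv <- matrix(runif(nr * nc, 0.5, 3), nr, nc)
    msk <- matrix(runif(nr * nc) < 0.7, nr, nc)
    sd_layer <- raster_grid(sdv, cell_size = 100)
    got <- aggregate_class_variance(sd_layer, msk, cg, cell_area_ha = 1,
                                    mode = "correlated")
    # literal O(n^2) double loop over masked pixels
    idx <- which(msk, arr.ind = TRUE)
    tot <- 0
    for (i in seq_len(nrow(idx))) {
      for (j in seq_len(nrow(idx))) {
        h <- 100 * sqrt(sum((idx[i, ] - idx[j, ])^2))
        rho <- if (h == 0) 1 else correlogram_rho(cg, h)
        tot <- tot + rho * sdv[idx[i, 1], idx[i, 2]] *
          sdv[idx[j, 1], idx[j, 2]]
      }
    }
    expect_equal(got$variance_TgC2, tot / 1e12, tolerance = 1e-10)
  }
})

test_that("aggregation closed forms, monotonicity and unit scaling hold", {
  # two pixels with SD 1 and rho = 0.5 -> variance 3, SD sqrt(3)
  cg <- structure(list(family = "exponential", nugget = 0,
                       partial_sill = 1, range_m = 100 / log(2),
                       effective_range_m = 1e6, converged = TRUE),
                  class = "correlogram_model")
  expect_equal(correlogram_rho(cg, 100), 0.5)
  sd2 <- raster_grid(matrix(1, 1, 2), cell_size = 100)
  got <- aggregate_class_variance(sd2, matrix(TRUE, 1, 2), cg,
                                  mode = "correlated")
  expect_equal(got$variance_TgC2 * 1e12, 3)
  expect_equal(got$sd_TgC * 1e6, sqrt(3), tolerance = 1e-12)

  # independence limit: SD = sqrt(sum SD_i^2)
  set.seed(14)
  sdv <- matrix(runif(36, 0.1, 2), 6, 6)
  ind <- aggregate_class_variance(raster_grid(sdv), matrix(TRUE, 6, 6),
                                  mode = "independent")
  expect_equal(ind$sd_TgC * 1e6, sqrt(sum(sdv^2)))

  # perfect correlation limit: SD = n x SD_pixel
  cg1 <- structure(list(family = "exponential", nugget = 0,
                        partial_sill = 1, range_m = 1e12,
                        effective_range_m = 1e13, converged = TRUE),
                   class = "correlogram_model")
  eq <- aggregate_class_variance(raster_grid(matrix(2, 4, 4)),
                                 matrix(TRUE, 4, 4), cg1,
                                 mode = "correlated")
  expect_equal(eq$sd_TgC * 1e6, 16 * 2, tolerance = 1e-9)

  # correlated-mode SD >= independent-mode SD and monotone in range
  sd_layer <- raster_grid(sdv, cell_size = 100)
  mk_cg <- function(r) structure(list(family = "exponential", nugget = 0.2,
                                      partial_sill = 0.8, range_m = r,
                                      effective_range_m = 3 * r,
                                      converged = TRUE),
                                 class = "correlogram_model")
  sds <- vapply(c(100, 300, 900), function(r)
    aggregate_class_variance(sd_layer, matrix(TRUE, 6, 6), mk_cg(r),
                             mode = "correlated")$sd_TgC, numeric(1))
  expect_equal(sds, sort(sds))
  expect_gte(sds[1], ind$sd_TgC)

  # doubling cell area doubles the class SD
  a1 <- aggregate_class_variance(sd_layer, matrix(TRUE, 6, 6),
                                 cell_area_ha = 1, mode = "independent")
  a2 <- aggregate_class_variance(sd_layer, matrix(TRUE, 6, 6),
                                 cell_area_ha = 2, mode = "independent")
  expect_equal(a2$sd_TgC, 2 * a1$sd_TgC)

  expect_error(aggregate_class_variance(sd_layer, matrix(TRUE, 6, 6),
                                        mode = "correlated"),
               "parameter error")
})

test_that("closing-stock variance adds opening and flux variances", {
  mk <- function(sd, cl = "mixed") structure(
    list(unseea_class = cl, n_pixels = 10, variance_TgC2 = sd^2,
         sd_TgC = sd, mode = "independent"), class = "class_variance")
  cl <- closing_stock_variance(mk(3), mk(4))
  expect_equal(cl$sd_TgC, 5)
  expect_equal(closing_stock_variance(mk(3), mk(0))$sd_TgC, 3)
  expect_gte(cl$sd_TgC, max(3, 4))
  expect_error(closing_stock_variance(mk(3), mk(4, "plantation")),
               "class mismatch")
})
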