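test_that("reclassification maps labels, resamples and overlays plantations", {
  labs <- c("broadleaved", "coniferous", "other_woody")
  lc <- raster_grid(matrix(c(1, 2, 3, 1), 2, 2), cell_size = 100,
                    levels = labs)
  out <- reclassify_landcover(lc, NULL)
  expect_equal(out$levels, unseea_account_classes())
  expect_equal(out$levels[out$values[1, 1]], "broadleaved")
  expect_equal(out$levels[out$values[1, 2]], "other_woody")

  # 300 m source becomes 3x3 blocks of identical 100 m labels
  lc300 <- raster_grid(matrix(c(1, 2, 2, 1), 2, 2), cell_size = 300,
                       levels = labs)
  out300 <- reclassify_landcover(lc300, NULL)
  expect_equal(dim(out300), c(6L, 6L))
  expect_true(all(out300$values[1:3, 1:3] == out300$values[1, 1]))

  # plantation overlay overrides a natural-forest label
  pm <- raster_grid(matrix(c(1, 0, 0, 0), 2, 2), cell_size = 100)
  outp <- reclassify_landcover(lc, pm)
  expect_equal(outp$levels[outp$values[1, 1]], "plantation")
  expect_equal(outp$levels[outp$values[2, 1]], "coniferous")

  # code mapping table with unmapped code -> error listing it
  lcc <- raster_grid(matrix(c(10, 20, 30, 99), 2, 2), cell_size = 100)
  map <- data.frame(source_code = c(10, 20, 30),
                    unseea_class = c("broadleaved", "mixed", "other_woody"))
  expect_error(reclassify_landcover(lcc, NULL, map), "99")
  map99 <- rbind(map, data.frame(source_code = 99, unseea_class = "mangroves"))
  outm <- reclassify_landcover(lcc, NULL, map99)
  expect_equal(outm$levels[outm$values[2, 2]], "mangroves")
  # pixel counts conserved
  expect_equal(sum(!is.na(outm$values)), 4)
})

test_that("class totals follow unit arithmetic and additivity", {
  # 1 pixel of 1 ha: opening 100 Mg C/ha -> 1e-4 Tg; flux -10 -> closing 9e-5
  op <- raster_grid(matrix(100, 1, 1))
  fl <- raster_grid(matrix(-10, 1, 1))
  cm <- raster_grid(matrix(1, 1, 1), levels = unseea_account_classes())
  tot <- class_totals(op, fl, cm, cell_area_ha = 1)
  expect_equal(tot$opening_TgC, 1e-4)
  expect_equal(tot$closing_TgC, 9e-5)
  expect_equal(tot$area_km2, 0.01)

  # zero flux: closing equals opening exactly
  set.seed(15)
  opn <- raster_grid(matrix(runif(100, 0, 200), 10, 10))
  zfl <- raster_grid(matrix(0, 10, 10))
  cm10 <- raster_grid(matrix(sample(1:3, 100, TRUE), 10, 10),
                      levels = unseea_account_classes())
  t0 <- class_totals(opn, zfl, cm10)
  expect_equal(t0$closing_TgC, t0$opening_TgC)

  # splitting one class into two masks reproduces the joint total
  flr <- raster_grid(matrix(rnorm(100, -5, 10), 10, 10))
  joint <- class_totals(opn, flr, cm10)
  split_map <- cm10$values
  split_map[split_map == 1][1:10] <- 4   # recode part of class 1 as mangroves
  cm_split <- raster_grid(split_map, levels = unseea_account_classes())
  parts <- class_totals(opn, flr, cm_split)
  expect_equal(sum(parts$flux_TgC[parts$unseea_class %in%
                                    c("broadleaved", "mangroves")]),
               joint$flux_TgC[joint$unseea_class == "broadleaved"])
})

test_that("emission split and attribution partition negative fluxes", {
  # hand-built 4-pixel class: fluxes (-2, -3, +1, 0)
  fl <- raster_grid(matrix(c(-2, -3, 1, 0), 2, 2))
  cm <- raster_grid(matrix(1, 2, 2), levels = unseea_account_classes())
  forest_lab <- c("broadleaved", "other_woody")
  # pixel (-2): forest->forest (degradation); pixel (-3): forest->non-forest
  lc10 <- raster_grid(matrix(c(1, 1, 1, 2), 2, 2),
                      levels = c("broadleaved", "bare"))
  lc18 <- raster_grid(matrix(c(1, 2, 1, 2), 2, 2),
                      levels = c("broadleaved", "bare"))
  sp <- emissions_split(fl, cm, lc10, lc18, forest_labels = "broadleaved")
  expect_equal(sp$net_emissions_TgC * 1e6, -5)
  expect_equal(sp$net_sequestration_TgC * 1e6, 1)
  expect_equal(sp$emissions_degradation_TgC * 1e6, -2)
  expect_equal(sp$emissions_conversion_TgC * 1e6, -3)
  expect_equal(sp$emissions_unattributed_TgC, 0)
  # partition is exhaustive
  expect_equal(sp$net_emissions_TgC,
               sp$emissions_degradation_TgC + sp$emissions_conversion_TgC +
                 sp$emissions_unattributed_TgC)

  # all-positive class has zero emissions
  flp <- raster_grid(matrix(2, 2, 2))
  spp <- emissions_split(flp, cm, lc10, lc18, forest_labels = "broadleaved")
  expect_equal(spp$net_emissions_TgC, 0)
  expect_error(emissions_split(fl, cm, lc10, lc18, forest_labels = character(0)),
               "parameter error")
})

test_that("account tables satisfy the accounting identities", {
  set.seed(16)
  for (rep in 1:5) {
    n_cls <- 4
    totals <- data.frame(
      unseea_class = unseea_account_classes()[1:n_cls],
      area_km2 = runif(n_cls, 10, 1000),
      opening_TgC = runif(n_cls, 1, 5000),
      flux_TgC = rnorm(n_cls, 0, 200))
    tab <- build_account_table(totals)
    body <- tab[tab$unseea_class != "total", ]
    expect_equal(body$closing_TgC, body$opening_TgC + body$flux_TgC,
                 tolerance = 1e-9)
    tot <- tab[tab$unseea_class == "total", ]
    expect_equal(tot$closing_TgC, sum(body$closing_TgC), tolerance = 1e-9)
    expect_equal(tot$closing_TgC, tot$opening_TgC + tot$flux_TgC,
                 tolerance = 1e-9)
  }
  # net flux = emissions + sequestration on a randomized raster account
  fl <- raster_grid(matrix(rnorm(400, 0, 10), 20, 20))
  op <- raster_grid(matrix(runif(400, 50, 150), 20, 20))
  cm <- raster_grid(matrix(sample(1:3, 400, TRUE), 20, 20),
                    levels = unseea_account_classes())
  lc <- raster_grid(matrix(1, 20, 20), levels = "broadleaved")
  tot <- class_totals(op, fl, cm)
  spl <- emissions_split(fl, cm, lc, lc)
  tab <- build_account_table(tot, splits = spl)
  body <- tab[tab$unseea_class != "total", ]
  expect_equal(body$flux_TgC,
               body$net_emissions_TgC + body$net_sequestration_TgC,
               tolerance = 1e-12)
})

test_that("variance wiring into the table uses independence addition", {
  mkv <- function(sd, cl) structure(
    list(unseea_class = cl, n_pixels = 5, variance_TgC2 = sd^2, sd_TgC = sd,
         mode = "independent"), class = "class_variance")
  totals <- data.frame(unseea_class = c("broadleaved", "mixed"),
                       area_km2 = c(10, 20), opening_TgC = c(100, 200),
                       flux_TgC = c(-5, 10))
  variances <- list(
    broadleaved = list(opening = mkv(3, "broadleaved"),
                       flux = mkv(4, "broadleaved")),
    mixed = list(opening = mkv(1, "mixed"), flux = mkv(2, "mixed")))
  tab <- build_account_table(totals, variances)
  expect_equal(tab$closing_sd_TgC[tab$unseea_class == "broadleaved"], 5)
  expect_equal(tab$closing_sd_TgC[tab$unseea_class == "mixed"], sqrt(5))
  expect_error(build_account_table(
    rbind(totals, data.frame(unseea_class = "plantation", area_km2 = 1,
                             opening_TgC = 1, flux_TgC = 0)), variances),
    "absent from variances")
})
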