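#' Reclassify land cover into UNSEEA accounting classes
#'
#' Maps source land-cover codes onto the six UNSEEA carbon-accounting
#' labels (broadleaved, coniferous, mixed, mangroves, other woody
#' vegetation, plantations) through a configurable mapping table,
#' resamples coarser sources to the working resolution by nearest
#' neighbour, and overlays the plantation mask: plantation pixels
#' override natural-forest labels, as the accounts require plantations to
#' be distinguished from natural forest.
#'
#' @param landcover categorical `raster_grid` (integer codes; a `levels`
#'   attribute supplies labels, otherwise codes are matched against
#'   `mapping$source_code`).
#' @param plantation_mask 0/1 `raster_grid` aligned with the target grid,
#'   or `NULL` for no overlay.
#' @param mapping data.frame with columns `source_code` (or
#'   `source_label`) and `unseea_class`; `NULL` accepts land cover whose
#'   level labels are already UNSEEA classes.
#' @param target_cell_m working resolution, m.
#' @return categorical `raster_grid` with levels
#'   [unseea_account_classes()].
#' @export
reclassify_landcover <- function(landcover, plantation_mask = NULL,
                                 mapping = NULL, target_cell_m = 100) {
  if (landcover$cell_size != target_cell_m) {
    landcover <- resample_nearest(landcover, target_cell_m)
  }
  target <- unseea_account_classes()
  v <- landcover$values
  if (is.null(mapping)) {
    if (is.null(landcover$levels)) {
      stop("mapping table required for land cover without class labels")
    }
    lab <- landcover$levels
    unk <- setdiff(lab[sort(unique(v[is.finite(v)]))], target)
    if (length(unk)) {
      stop("unmapped source code(s): ", paste(unk, collapse = ", "))
    }
    out_code <- match(lab, target)[v]
  } else {
    key <- if ("source_label" %in% names(mapping) && !is.null(landcover$levels)) {
      match(landcover$levels[v], mapping$source_label)
    } else {
      match(v, mapping$source_code)
    }
    bad <- is.finite(v) & is.na(key)
    if (any(bad)) {
      codes <- unique(v[bad])
      stop("unmapped source code(s): ", paste(codes, collapse = ", "))
    }
    unk <- setdiff(unique(mapping$unseea_class), target)
    if (length(unk)) stop("unknown UNSEEA class in mapping: ",
                          paste(unk, collapse = ", "))
    out_code <- match(mapping$unseea_class, target)[key]
  }
  out <- matrix(out_code, nrow(v), ncol(v))
  if (!is.null(plantation_mask)) {
    if (plantation_mask$cell_size != target_cell_m) {
      plantation_mask <- resample_nearest(plantation_mask, target_cell_m)
    }
    pm <- plantation_mask$values > 0 & !is.na(plantation_mask$values)
    out[pm & !is.na(out)] <- match("plantation", target)
  }
  raster_grid(out, cell_size = target_cell_m, xll = landcover$xll,
              yll = landcover$yll, levels = target)
}

#' UNSEEA carbon-accounting class labels
#' @return character vector of the six Level-2 class labels.
#' @export
unseea_account_classes <- function() {
  c("broadleaved", "coniferous", "mixed", "mangroves", "other_woody",
    "plantation")
}

#' Per-class opening, flux and closing totals
#'
#' Sums per-pixel stocks and fluxes (Mg C ha^-1 x cell area) within each
#' UNSEEA class into Tg C totals; the closing stock is the per-pixel sum
#' of opening plus signed net flux, which by linearity equals the sum of
#' the class totals. Areas are reported in km^2.
#'
#' @param opening_stock `raster_grid`, Mg C ha^-1.
#' @param flux `raster_grid`, signed Mg C ha^-1 over the period.
#' @param classmap categorical `raster_grid` of UNSEEA classes.
#' @param cell_area_ha cell area, ha.
#' @return data.frame: `unseea_class`, `n_pixels`, `area_km2`,
#'   `opening_TgC`, `flux_TgC`, `closing_TgC`.
#' @export
class_totals <- function(opening_stock, flux, classmap, cell_area_ha = 1) {
  check_aligned(opening_stock, flux, classmap)
  labs <- classmap$levels
  if (is.null(labs)) stop("classmap must carry class labels")
  cls <- classmap$values
  ok <- is.finite(cls) & is.finite(opening_stock$values) &
    is.finite(flux$values)
  rows <- lapply(seq_along(labs), function(cd) {
    inc <- ok & cls == cd
    n <- sum(inc)
    if (n == 0) return(NULL)
    op <- sum(opening_stock$values[inc]) * cell_area_ha / 1e6
    fl <- sum(flux$values[inc]) * cell_area_ha / 1e6
    data.frame(unseea_class = labs[cd], n_pixels = n,
               area_km2 = n * cell_area_ha / 100,
               opening_TgC = op, flux_TgC = fl, closing_TgC = op + fl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no valid pixels in any class")
  out
}

#' Emission/sequestration split with conversion-degradation attribution
#'
#' Per UNSEEA class, net emissions are the sum of negative-flux pixels
#' and net sequestration the sum of positive-flux pixels (zero-flux
#' pixels contribute to neither). Negative-flux pixels that were forest
#' in both land-cover epochs are attributed to forest degradation; those
#' forest in 2010 but non-forest in 2018 to forest conversion; negative
#' pixels not forest in 2010 (possible under other woody vegetation) go
#' to a residual unattributed column so the partition stays exhaustive.
#'
#' @param flux `raster_grid`, signed Mg C ha^-1.
#' @param classmap categorical UNSEEA `raster_grid`.
#' @param landcover_2010,landcover_2018 categorical `raster_grid`s whose
#'   labels include the forest classes.
#' @param forest_labels labels counted as forest; default
#'   [forest_classes()].
#' @param cell_area_ha cell area, ha.
#' @return data.frame per class: `net_emissions_TgC` (<= 0),
#'   `net_sequestration_TgC` (>= 0), `emissions_degradation_TgC`,
#'   `emissions_conversion_TgC`, `emissions_unattributed_TgC`.
#' @export
emissions_split <- function(flux, classmap, landcover_2010, landcover_2018,
                            forest_labels = forest_classes(),
                            cell_area_ha = 1) {
  if (!length(forest_labels)) stop("parameter error: forest_labels is empty")
  check_aligned(flux, classmap, landcover_2010, landcover_2018)
  labs <- classmap$levels
  lab10 <- landcover_2010$levels; lab18 <- landcover_2018$levels
  f10 <- matrix(lab10[landcover_2010$values] %in% forest_labels,
                nrow(flux$values), ncol(flux$values))
  f18 <- matrix(lab18[landcover_2018$values] %in% forest_labels,
                nrow(flux$values), ncol(flux$values))
  fx <- flux$values
  cls <- classmap$values
  ok <- is.finite(fx) & is.finite(cls)
  rows <- lapply(seq_along(labs), function(cd) {
    inc <- ok & cls == cd
    if (!any(inc)) return(NULL)
    neg <- inc & fx < 0
    pos <- inc & fx > 0
    tg <- function(sel) sum(fx[sel]) * cell_area_ha / 1e6
    data.frame(
      unseea_class = labs[cd],
      net_emissions_TgC = tg(neg),
      net_sequestration_TgC = tg(pos),
      emissions_degradation_TgC = tg(neg & f10 & f18),
      emissions_conversion_TgC = tg(neg & f10 & !f18),
      emissions_unattributed_TgC = tg(neg & !f10),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the UNSEEA carbon accounting table
#'
#' One row per UNSEEA class in account order (area, opening +/- SD, net
#' flux +/- SD, closing +/- SD), extended with the emission/sequestration
#' split when supplied, plus a totals row. The closing stock is
#' opening + signed net flux; its SD adds the opening and flux variances
#' ([closing_stock_variance()]). Classes absent from the totals are
#' omitted with a message.
#'
#' @param totals data.frame from [class_totals()] — or any data.frame
#'   with `unseea_class`, `area_km2`, `opening_TgC`, `flux_TgC` (closing
#'   recomputed as their sum).
#' @param variances optional named list per class, each with
#'   `opening` and `flux` [aggregate_class_variance()] results.
#' @param splits optional data.frame from [emissions_split()].
#' @return object of class `account_table` (a data.frame with a totals
#'   row last).
#' @export
build_account_table <- function(totals, variances = NULL, splits = NULL) {
  need <- c("unseea_class", "area_km2", "opening_TgC", "flux_TgC")
  miss <- setdiff(need, names(totals))
  if (length(miss)) stop("totals missing columns: ", paste(miss, collapse = ", "))
  tab <- totals[, need, drop = FALSE]
  tab$closing_TgC <- tab$opening_TgC + tab$flux_TgC
  if (!is.null(variances)) {
    absent <- setdiff(tab$unseea_class, names(variances))
    if (length(absent)) {
      stop("class present in map but absent from variances: ",
           paste(absent, collapse = ", "))
    }
    tab$opening_sd_TgC <- vapply(tab$unseea_class, function(cl)
      variances[[cl]]$opening$sd_TgC, numeric(1))
    tab$flux_sd_TgC <- vapply(tab$unseea_class, function(cl)
      variances[[cl]]$flux$sd_TgC, numeric(1))
    tab$closing_sd_TgC <- vapply(tab$unseea_class, function(cl)
      closing_stock_variance(variances[[cl]]$opening,
                             variances[[cl]]$flux)$sd_TgC, numeric(1))
  }
  if (!is.null(splits)) {
    tab <- merge(tab, splits, by = "unseea_class", all.x = TRUE, sort = FALSE)
  }
  ord <- match(tab$unseea_class, unseea_account_classes())
  tab <- tab[order(ord), , drop = FALSE]
  tot <- tab[1, , drop = FALSE]
  tot$unseea_class <- "total"
  for (cn in setdiff(names(tab), "unseea_class")) {
    tot[[cn]] <- if (grepl("_sd_", cn)) {
      sqrt(sum(tab[[cn]]^2))       # classes treated as independent
    } else {
      sum(tab[[cn]])
    }
  }
  out <- rbind(tab, tot)
  rownames(out) <- NULL
  class(out) <- c("account_table", "data.frame")
  out
}

#' @export
print.account_table <- function(x, ...) {
  df <- as.data.frame(x)
  fmt <- function(v, sd) {
    if (is.null(sd)) sprintf("%.2f", v)
    else sprintf("%.2f +/- %.3f", v, sd)
  }
  cat("UNSEEA carbon account (Tg C; negative flux = net emission)\n")
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-14s area %10.0f km2 | opening %s | flux %s | closing %s\n",
                df$unseea_class[i], df$area_km2[i],
                fmt(df$opening_TgC[i], df$opening_sd_TgC[i]),
                fmt(df$flux_TgC[i], df$flux_sd_TgC[i]),
                fmt(df$closing_TgC[i], df$closing_sd_TgC[i])))
  }
  invisible(x)
}

#' Write an account table as CSV
#'
#' @param table an [build_account_table()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_account_csv <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 9))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
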