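#' Feature-space dissimilarity index
#'
#' Measures how far each pixel lies from the reference sample in the
#' multidimensional covariate space. Each retained continuous covariate
#' is standardized by its training mean/SD and scaled by its normalized
#' importance; the dissimilarity index (DI) of a pixel is its Euclidean
#' distance in this weighted space to the nearest training plot, divided
#' by the mean pairwise distance among the training plots. DI is 0 at
#' cells containing a training plot and grows without bound in
#' extrapolation areas. Only continuous covariates enter the metric:
#' Euclidean distance on one-hot codes would dominate it.
#'
#' @param stack a [covariate_stack()].
#' @param design a [extract_at_plots()] design matrix (training plots).
#' @param importance named non-negative importance per retained
#'   continuous covariate; equal weights when `NULL`.
#' @return `raster_grid` of DI values (missing where any covariate is
#'   missing).
#' @export
compute_dissimilarity <- function(stack, design, importance = NULL) {
  feats <- design$covariates[design$kind_tags[design$covariates] == "continuous"]
  if (!length(feats)) stop("no continuous covariates for the dissimilarity index")
  if (nrow(design$X) < 2) stop("at least 2 training plots are required")
  if (is.null(importance)) {
    importance <- stats::setNames(rep(1, length(feats)), feats)
  }
  if (any(is.na(importance[feats])) || any(importance[feats] < 0)) {
    stop("importance must be non-negative and defined for every continuous covariate")
  }
  w <- importance[feats] / sum(importance[feats])
  tr <- design$X[, feats, drop = FALSE]
  mu <- colMeans(tr)
  sdv <- apply(tr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  tw <- sweep(sweep(tr, 2, mu), 2, sdv, "/")
  tw <- sweep(tw, 2, w, "*")
  # mean pairwise distance among training plots
  dbar <- mean(stats::dist(tw))
  if (dbar == 0) dbar <- 1  # degenerate: all plots identical
  ref <- stack$layers[[feats[1]]]
  n_cell <- length(ref$values)
  di <- rep(NA_real_, n_cell)
  tnorm2 <- rowSums(tw^2)
  chunk <- 20000L
  for (st in seq(1L, n_cell, by = chunk)) {
    cells <- st:min(st + chunk - 1L, n_cell)
    px <- sapply(feats, function(n) stack$layers[[n]]$values[cells])
    px <- matrix(px, nrow = length(cells))
    ok <- stats::complete.cases(px)
    if (!any(ok)) next
    pw <- sweep(sweep(px[ok, , drop = FALSE], 2, mu), 2, sdv, "/")
    pw <- sweep(pw, 2, w, "*")
    d2 <- outer(rowSums(pw^2), tnorm2, "+") - 2 * pw %*% t(tw)
    d2[d2 < 1e-10] <- 0   # clamp cancellation noise so DI = 0 at plots
    di[cells[ok]] <- sqrt(apply(d2, 1, min)) / dbar
  }
  raster_grid(matrix(di, nrow(ref$values), ncol(ref$values)),
              cell_size = ref$cell_size, xll = ref$xll, yll = ref$yll)
}

#' Under-sampling threshold from cross-validated training DI
#'
#' For each training plot, the DI to its nearest plot outside its
#' cross-validation fold is computed (same standardization and importance
#' weighting as [compute_dissimilarity()], same mean-pairwise-distance
#' normalization); the threshold is Q3 + 1.5 IQR of these training DI
#' values — the conventional upper-whisker rule.
#'
#' @inheritParams compute_dissimilarity
#' @param k number of folds.
#' @param seed seed for the fold assignment.
#' @return threshold (non-negative scalar).
#' @export
coverage_threshold <- function(design, importance = NULL, k = 5, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  feats <- design$covariates[design$kind_tags[design$covariates] == "continuous"]
  if (is.null(importance)) {
    importance <- stats::setNames(rep(1, length(feats)), feats)
  }
  w <- importance[feats] / sum(importance[feats])
  tr <- design$X[, feats, drop = FALSE]
  mu <- colMeans(tr); sdv <- apply(tr, 2, stats::sd); sdv[sdv == 0] <- 1
  tw <- sweep(sweep(sweep(tr, 2, mu), 2, sdv, "/"), 2, w, "*")
  dm <- as.matrix(stats::dist(tw))
  dbar <- mean(dm[upper.tri(dm)])
  if (dbar == 0) {
    warning("all training plots identical in feature space; threshold 0")
    return(0)
  }
  folds <- kfold_split(nrow(tw), k = k, seed = seed)
  di <- vapply(seq_len(nrow(tw)), function(i) {
    out <- folds != folds[i]
    min(dm[i, out]) / dbar
  }, numeric(1))
  q <- stats::quantile(di, c(0.25, 0.75), names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Under-sampled area report
#'
#' Flags pixels whose DI exceeds the threshold and reports the share of
#' flagged pixels among valid (vegetated) pixels, overall and per UNSEEA
#' class. Classes with no valid pixels report `NA`, not 0.
#'
#' @param dissimilarity `raster_grid` from [compute_dissimilarity()].
#' @param threshold scalar from [coverage_threshold()].
#' @param unseea_map categorical `raster_grid` of UNSEEA classes; its
#'   valid pixels define the vegetated area.
#' @return object of class `coverage_result`: the mask, `fraction_total`
#'   and `fraction_by_class`.
#' @export
undersampled_report <- function(dissimilarity, threshold, unseea_map) {
  check_aligned(dissimilarity, unseea_map)
  valid <- is.finite(dissimilarity$values) & is.finite(unseea_map$values)
  mask <- dissimilarity$values > threshold & valid
  labs <- unseea_map$levels
  if (is.null(labs)) {
    labs <- as.character(sort(unique(unseea_map$values[valid])))
    codes <- sort(unique(unseea_map$values[valid]))
  } else {
    codes <- seq_along(labs)
  }
  by_class <- vapply(codes, function(cd) {
    inc <- valid & unseea_map$values == cd
    if (!any(inc)) return(NA_real_)
    mean(mask[inc])
  }, numeric(1))
  names(by_class) <- labs
  structure(list(
    dissimilarity = dissimilarity, threshold = threshold,
    undersampled_mask = raster_grid(
      ifelse(valid, mask + 0, NA_real_),
      cell_size = dissimilarity$cell_size,
      xll = dissimilarity$xll, yll = dissimilarity$yll),
    fraction_total = if (any(valid)) mean(mask[valid]) else NA_real_,
    fraction_by_class = by_class
  ), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage_result: threshold %.3f, %.1f%% of valid area under-sampled\n",
              x$threshold, 100 * x$fraction_total))
  for (nm in names(x$fraction_by_class)) {
    cat(sprintf("  %-18s %s\n", nm,
                ifelse(is.na(x$fraction_by_class[[nm]]), "undefined",
                       sprintf("%.1f%%", 100 * x$fraction_by_class[[nm]]))))
  }
  invisible(x)
}
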