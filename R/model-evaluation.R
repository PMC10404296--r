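#' Random k-fold partition
#'
#' Random partition of `n` indices into `k` folds with sizes differing by
#' at most 1; deterministic given the seed.
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k) of length `n`.
#' @export
kfold_split <- function(n, k = 5, seed = 1L) {
  if (n < k) stop("n must be >= k")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Map accuracy metrics
#'
#' RMSE = sqrt(mean((z - zhat)^2)); ME = mean(z - zhat) (observed minus
#' predicted, so positive ME means under-prediction); R^2 = 1 - SSE/SST
#' with the total sum of squares about the mean of the observations in
#' the evaluated set.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return list with `rmse`, `me`, `r2`, `n`. `r2` is `NA` (with a
#'   warning) when the observations have zero variance.
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2) stop("need at least 2 observations")
  e <- observed - predicted
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst == 0) {
    warning("zero variance in observed values; R^2 undefined")
    NA_real_
  } else 1 - sum(e^2) / sst
  list(rmse = sqrt(mean(e^2)), me = mean(e), r2 = r2, n = length(observed))
}

#' Five-fold cross-validation of the stacked ensemble
#'
#' For each fold the full ensemble (base learners with their own nested
#' out-of-fold discipline, then the meta learner) is refit without the
#' fold and scored on it with [compute_metrics()]. The unweighted mean
#' and SD of each metric across folds are reported; case weights affect
#' fitting only.
#'
#' @param design a [extract_at_plots()] design matrix.
#' @param specs list of 3 tuned [learner_spec()]s.
#' @param k number of folds.
#' @param seed integer seed (folds and learner fits).
#' @return object of class `cv_result`: `per_fold` data.frame and
#'   `summary` (mean and sd of rmse/me/r2).
#' @export
cross_validate <- function(design, specs, k = 5, seed = 1L) {
  n <- nrow(design$X)
  folds <- kfold_split(n, k = k, seed = derive_seed(seed, 11L))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    sub <- subset_design(design, tr)
    fit <- fit_stacked_ensemble(sub, specs, k = k,
                                seed = derive_seed(seed, 100L + f))
    pred <- predict(fit, design$X[!tr, , drop = FALSE])
    m <- compute_metrics(design$response[!tr], pred$mean)
    rows[[f]] <- data.frame(fold = f, rmse = m$rmse, me = m$me,
                            r2 = m$r2, n = m$n)
  }
  per_fold <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("rmse", "me", "r2"),
    mean = c(mean(per_fold$rmse), mean(per_fold$me), mean(per_fold$r2)),
    sd = c(stats::sd(per_fold$rmse), stats::sd(per_fold$me),
           stats::sd(per_fold$r2))
  )
  structure(list(per_fold = per_fold, summary = summ, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d-fold cross-validation (n = %d)\n", x$k, sum(x$per_fold$n)))
  cat(sprintf("  RMSE %.2f +/- %.2f Mg C/ha | ME %.2f +/- %.2f | R2 %.2f +/- %.2f\n",
              s$mean[1], s$sd[1], s$mean[2], s$sd[2], s$mean[3], s$sd[3]))
  invisible(x)
}

# Row subset of a design matrix, keeping the encoding metadata.
subset_design <- function(design, keep) {
  design$X <- design$X[keep, , drop = FALSE]
  design$response <- design$response[keep]
  design$weights <- design$weights[keep]
  design$coords <- design$coords[keep, , drop = FALSE]
  design$plot_id <- design$plot_id[keep]
  design
}
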