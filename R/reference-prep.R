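#' Reference plot set
#'
#' Ordered table of quality-flagged reference plots. Each record carries a
#' signed net flux observation (biomass or carbon depending on
#' `units_note`), its measurement variance, an inverse-variance case
#' weight (filled by [compute_case_weights()]), coordinates, a source tag
#' (NFI field plots or LiDAR map pixels) and the two quality flags used
#' for filtering.
#'
#' @param records data.frame with columns `plot_id`, `x`, `y`,
#'   `flux_obs`, `flux_var`, `source`, `forest_change_flag`, `edge_flag`
#'   (and optionally `weight`).
#' @param design_tag sampling design of the set.
#' @param units_note `"biomass"` or `"carbon"`; [biomass_to_carbon()]
#'   switches the former to the latter.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(records,
                          design_tag = c("uniform", "systematic",
                                         "clustered", "stratified"),
                          units_note = c("carbon", "biomass")) {
  design_tag <- match.arg(design_tag)
  units_note <- match.arg(units_note)
  need <- c("plot_id", "x", "y", "flux_obs", "flux_var", "source",
            "forest_change_flag", "edge_flag")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$plot_id)) stop("plot_id values must be unique")
  if (any(records$flux_var < 0, na.rm = TRUE)) stop("flux_var must be >= 0")
  if (any(!is.finite(records$x)) || any(!is.finite(records$y))) {
    stop("plot coordinates must be finite")
  }
  if (is.null(records$weight)) records$weight <- NA_real_
  structure(list(records = records, design_tag = design_tag,
                 units_note = units_note),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d plots (%s design, %s units)\n",
              nrow(x$records), x$design_tag, x$units_note))
  invisible(x)
}

#' Quality-filter reference plots
#'
#' Retains only plots without forest-area change since the latest
#' measurement and not on LiDAR footprint edges (partial pixel overlap),
#' i.e. records with both quality flags FALSE. Order is preserved and the
#' removed count is reported via message.
#'
#' @param refset a [reference_set()].
#' @return the filtered `reference_set`.
#' @export
filter_plots <- function(refset) {
  rec <- refset$records
  keep <- !rec$forest_change_flag & !rec$edge_flag
  if (!any(keep)) stop("all plots removed by quality filtering; cannot fit a model")
  message(sprintf("filter_plots: removed %d of %d plots (%d forest-change, %d edge)",
                  sum(!keep), nrow(rec), sum(rec$forest_change_flag),
                  sum(rec$edge_flag & !rec$forest_change_flag)))
  refset$records <- rec[keep, , drop = FALSE]
  refset
}

#' Convert biomass change to carbon flux
#'
#' Multiplies the observed net above-ground biomass change by the carbon
#' fraction (default 0.49) and the variance by its square, and switches
#' the units note to carbon. Converting an already-converted set is an
#' error.
#'
#' @param refset a [reference_set()] with `units_note = "biomass"`.
#' @param fraction carbon fraction of dry biomass.
#' @return the converted `reference_set`.
#' @export
biomass_to_carbon <- function(refset, fraction = 0.49) {
  if (refset$units_note != "biomass") {
    stop("state error: units are already carbon; refusing a double conversion")
  }
  refset$records$flux_obs <- refset$records$flux_obs * fraction
  refset$records$flux_var <- refset$records$flux_var * fraction^2
  refset$units_note <- "carbon"
  refset
}

#' Fill plot measurement variances
#'
#' NFI plot uncertainties are modelled as a relative SD of the observed
#' flux with an absolute floor (so variances never vanish):
#' `flux_var = (nfi_relative_sd * max(|flux_obs|, floor))^2` for NFI
#' records with no supplied variance. LiDAR records (and any record with
#' a supplied variance) keep their values, which come from per-pixel
#' uncertainty layers.
#'
#' @param refset a [reference_set()].
#' @param nfi_relative_sd relative SD of NFI flux measurements.
#' @param floor absolute flux floor, Mg C ha^-1.
#' @return the `reference_set` with `flux_var` populated.
#' @export
estimate_plot_variance <- function(refset, nfi_relative_sd = 0.2, floor = 1) {
  if (nfi_relative_sd < 0) stop("parameter error: relative SD must be >= 0")
  rec <- refset$records
  fill <- rec$source == "NFI" & (is.na(rec$flux_var) | rec$flux_var == 0)
  rec$flux_var[fill] <- (nfi_relative_sd * pmax(abs(rec$flux_obs[fill]), floor))^2
  refset$records <- rec
  refset
}

#' Inverse-variance case weights
#'
#' weight_i = (1 / var_i) / mean_j(1 / var_j), so less uncertain plots get
#' larger weights and the mean weight is 1 (the effective sample size is
#' unchanged, keeping learner defaults meaningful).
#'
#' @param refset a [reference_set()] with strictly positive `flux_var`.
#' @return the `reference_set` with `weight` filled.
#' @export
compute_case_weights <- function(refset) {
  v <- refset$records$flux_var
  if (any(is.na(v) | v <= 0)) {
    stop("zero or missing plot variance; apply estimate_plot_variance() ",
         "with a positive floor first")
  }
  inv <- 1 / v
  refset$records$weight <- inv / mean(inv)
  refset
}

#' Read and write the reference-plot CSV dialect
#'
#' Header: plot_id,x,y,flux_obs,flux_var,source,forest_change_flag,edge_flag
#' (plus `weight` when present).
#'
#' @param refset a [reference_set()].
#' @param path file path.
#' @param design_tag,units_note metadata for the set read from disk.
#' @return `write_plots_csv` returns `path` invisibly; `read_plots_csv` a
#'   `reference_set`.
#' @export
write_plots_csv <- function(refset, path) {
  utils::write.csv(refset$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plots_csv
#' @export
read_plots_csv <- function(path, design_tag = "uniform",
                           units_note = "carbon") {
  reference_set(utils::read.csv(path, stringsAsFactors = FALSE),
                design_tag = design_tag, units_note = units_note)
}
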