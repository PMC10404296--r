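#' Georeferenced single-variable grid
#'
#' Minimal container for one variable on an equal-area grid: a numeric
#' matrix plus cell size and lower-left origin. Matrix rows follow the
#' usual raster convention (row 1 is the northernmost row); missing cells
#' are `NA`. Categorical grids carry a `levels` attribute mapping integer
#' codes to labels.
#'
#' @param values numeric or integer matrix (row 1 = top of the map).
#' @param cell_size cell edge length in metres (equal-area grid assumed).
#' @param xll,yll coordinates of the lower-left corner of the grid, m.
#' @param levels optional character vector of class labels for categorical
#'   grids; cell values are then 1-based codes into this vector.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 100, xll = 0, yll = 0,
                        levels = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a positive number")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll), levels = levels),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  kind <- if (is.null(x$levels)) "continuous" else
    sprintf("categorical (%d classes)", length(x$levels))
  cat(sprintf("raster_grid: %d x %d cells, %g m resolution, %s\n",
              d[1], d[2], x$cell_size, kind))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d valid cells)\n",
                min(v), mean(v), max(v), length(v)))
  } else {
    cat("  values: all missing\n")
  }
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a `raster_grid`.
#' @return list with matrices/vectors `x` (per column) and `y` (per row).
#' @keywords internal
grid_centres <- function(grid) {
  d <- dim(grid$values)
  list(
    x = grid$xll + (seq_len(d[2]) - 0.5) * grid$cell_size,
    y = grid$yll + (d[1] - seq_len(d[1]) + 0.5) * grid$cell_size
  )
}

#' Map point coordinates to grid row/column indices
#'
#' Point-in-cell lookup: each point is assigned the cell whose extent
#' contains it. Points outside the grid get `NA` indices.
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates in grid units (m).
#' @return data.frame with columns `row`, `col`.
#' @export
cell_index <- function(grid, x, y) {
  d <- dim(grid$values)
  col <- floor((x - grid$xll) / grid$cell_size) + 1L
  row <- d[1] - floor((y - grid$yll) / grid$cell_size)
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' @inheritParams cell_index
#' @return numeric vector of cell values (`NA` outside the grid or at
#'   missing cells).
#' @export
extract_cells <- function(grid, x, y) {
  idx <- cell_index(grid, x, y)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$row)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Nearest-neighbour resampling to a finer or equal cell size
#'
#' Replicates source cells onto a target resolution that divides the
#' source cell size evenly (e.g. 300 m categorical land cover onto the
#' 100 m working grid), matching nearest-neighbour interpolation for
#' aligned grids.
#'
#' @param grid a `raster_grid`.
#' @param target_cell target cell size in m; `grid$cell_size` must be an
#'   integer multiple of it.
#' @return a `raster_grid` at the target resolution.
#' @export
resample_nearest <- function(grid, target_cell) {
  f <- grid$cell_size / target_cell
  if (abs(f - round(f)) > 1e-9 || f < 1) {
    stop("source cell size must be an integer multiple of `target_cell`")
  }
  f <- as.integer(round(f))
  v <- grid$values[rep(seq_len(nrow(grid$values)), each = f),
                   rep(seq_len(ncol(grid$values)), each = f), drop = FALSE]
  raster_grid(v, cell_size = target_cell, xll = grid$xll, yll = grid$yll,
              levels = grid$levels)
}

#' Read and write Esri ASCII grids
#'
#' Plain-text raster interchange used for all on-disk grids. The writer
#' stores the nodata sentinel -9999; categorical level labels are not
#' persisted (store the mapping table separately).
#'
#' @param grid a `raster_grid`.
#' @param path file path.
#' @param digits significant digits written.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `raster_grid`.
#' @export
write_ascii_grid <- function(grid, path, digits = 7) {
  d <- dim(grid$values)
  v <- grid$values
  v[!is.finite(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.6f", grid$xll),
    sprintf("yllcorner %.6f", grid$yll),
    sprintf("cellsize %.6f", grid$cell_size),
    "NODATA_value -9999"
  ), con)
  apply(v, 1, function(r) {
    writeLines(paste(signif(r, digits), collapse = " "), con)
  })
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  val <- vapply(hdr, function(h) as.numeric(h[2]), numeric(1))
  names(val) <- vapply(hdr, `[[`, character(1), 1)
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- do.call(rbind, lapply(body, as.numeric))
  m[m == val[["nodata_value"]]] <- NA_real_
  raster_grid(m, cell_size = val[["cellsize"]],
              xll = val[["xllcorner"]], yll = val[["yllcorner"]])
}

# Shared guard: all grids in `...` must agree in shape and cell size.
check_aligned <- function(...) {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        !isTRUE(all.equal(g$cell_size, ref$cell_size))) {
      stop("rasters are not aligned (shape or cell size differs)")
    }
  }
  invisible(TRUE)
}
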