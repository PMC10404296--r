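#' Covariate stack
#'
#' Named collection of aligned covariate layers with per-layer kind
#' (continuous or categorical) and covariate-category tags. Categories
#' follow the covariate-table convention used for importance aggregation
#' (global biomass products CCI/Flux/AGB/CONUS, environmental dynamics,
#' land cover, management, topography, climate).
#'
#' @param layers named list of aligned `raster_grid` layers.
#' @param kind_tags named character vector, `"continuous"` or
#'   `"categorical"` per layer; inferred from the presence of class
#'   levels when omitted.
#' @param category_tags named character vector of category labels per
#'   layer; defaults to `"envi"`.
#' @return object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, kind_tags = NULL, category_tags = NULL) {
  if (is.null(names(layers)) || anyDuplicated(names(layers))) {
    stop("layers must be uniquely named")
  }
  do.call(check_aligned, layers)
  nm <- names(layers)
  if (is.null(kind_tags)) {
    kind_tags <- vapply(layers, function(l)
      if (is.null(l$levels)) "continuous" else "categorical", character(1))
  }
  if (is.null(category_tags)) {
    category_tags <- stats::setNames(rep("envi", length(nm)), nm)
  }
  if (!all(nm %in% names(kind_tags)) || !all(nm %in% names(category_tags))) {
    stop("every layer must have a kind tag and a category tag")
  }
  structure(list(layers = layers, kind_tags = kind_tags[nm],
                 category_tags = category_tags[nm]),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("covariate_stack: %d layers (%d continuous, %d categorical)\n",
              length(x$layers), sum(x$kind_tags == "continuous"),
              sum(x$kind_tags == "categorical")))
  invisible(x)
}

# Summed-area table with a zero top/left border.
sat <- function(m) {
  s <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  s[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  s
}

# Sum of `m` over the rectangle [r1..r2] x [c1..c2] for every window
# centre, where r1/r2/c1/c2 are contiguous index ranges; `s` is sat(m).
rect_sum <- function(s, r1, r2, c1, c2) {
  s[r2 + 1, c2 + 1, drop = FALSE] - s[r1, c2 + 1, drop = FALSE] -
    s[r2 + 1, c1, drop = FALSE] + s[r1, c1, drop = FALSE]
}

#' Windowed gray-level co-occurrence texture statistics
#'
#' For each centre pixel whose square window lies fully inside the raster
#' and contains no missing cells, window values are quantized into
#' `gray_levels` equal-width bins over the layer's global finite range,
#' the symmetric normalized co-occurrence matrix P is accumulated over
#' the pooled offsets (0,1), (1,0), (1,1), (1,-1) (pairs with both cells
#' in the window), and four statistics are returned: mean
#' (sum i P(i,j)), variance (sum (i - mean)^2 P(i,j)), homogeneity
#' (sum P(i,j) / (1 + (i-j)^2)) and contrast (sum (i-j)^2 P(i,j)).
#' A constant layer maps every cell to one level, giving homogeneity 1
#' and contrast/variance 0. Level indices are 1-based.
#'
#' The default 3 x 3 window corresponds to a 300 x 300 m texture
#' neighbourhood at the 100 m working resolution.
#'
#' @param layer a continuous `raster_grid`.
#' @param window_cells odd window edge length in cells.
#' @param gray_levels number of quantization levels (>= 2).
#' @return named list of `raster_grid`s: `texMean`, `texVar`, `texHomo`,
#'   `texContrast`.
#' @export
compute_glcm_textures <- function(layer, window_cells = 3, gray_levels = 32) {
  if (window_cells %% 2 != 1 || window_cells < 3) {
    stop("window_cells must be odd and >= 3")
  }
  if (gray_levels < 2) stop("gray_levels must be >= 2")
  v <- layer$values
  nr <- nrow(v); nc <- ncol(v)
  m <- (window_cells - 1) / 2
  if (nr < window_cells || nc < window_cells) stop("raster smaller than window")
  q <- quantize_levels(v, gray_levels)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  I <- (m + 1):(nr - m); J <- (m + 1):(nc - m)
  N <- S1 <- S2 <- CC <- HH <- matrix(0, length(I), length(J))
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    a <- matrix(NA_real_, nr, nc); b <- matrix(NA_real_, nr, nc)
    rr <- 1:(nr - dr)
    cc <- (1 - min(dc, 0)):(nc - max(dc, 0))
    a[rr, cc] <- q[rr, cc]
    b[rr, cc] <- q[rr + dr, cc + dc]
    ok <- is.finite(a) & is.finite(b)
    z <- function(x) { x[!ok] <- 0; x }
    s_cnt <- sat(ok + 0)
    s_s1 <- sat(z(a + b)); s_s2 <- sat(z(a^2 + b^2))
    s_cc <- sat(z((a - b)^2)); s_hh <- sat(z(1 / (1 + (a - b)^2)))
    r1 <- I - m; r2 <- I + m - dr
    c1 <- J - m - min(dc, 0); c2 <- J + m - max(dc, 0)
    N <- N + rect_sum(s_cnt, r1, r2, c1, c2)
    S1 <- S1 + rect_sum(s_s1, r1, r2, c1, c2)
    S2 <- S2 + rect_sum(s_s2, r1, r2, c1, c2)
    CC <- CC + rect_sum(s_cc, r1, r2, c1, c2)
    HH <- HH + rect_sum(s_hh, r1, r2, c1, c2)
  }
  # windows touched by any missing cell are nodata
  s_na <- sat(is.na(v) + 0)
  n_na <- rect_sum(s_na, I - m, I + m, J - m, J + m)
  bad <- n_na > 0 | N == 0
  mu <- S1 / (2 * N)
  tex <- list(
    texMean = mu,
    texVar = S2 / (2 * N) - mu^2,
    texHomo = HH / N,
    texContrast = CC / N
  )
  lapply(tex, function(t) {
    t[bad] <- NA_real_
    out <- matrix(NA_real_, nr, nc)
    out[I, J] <- t
    # clamp tiny negative variance from floating-point cancellation
    out[is.finite(out) & out < 0 & out > -1e-9] <- 0
    raster_grid(out, cell_size = layer$cell_size, xll = layer$xll,
                yll = layer$yll)
  })
}

# Equal-width quantization over the global finite range into 1..L.
quantize_levels <- function(v, levels) {
  fin <- is.finite(v)
  if (!any(fin)) return(v)
  rng <- range(v[fin])
  q <- matrix(NA_real_, nrow(v), ncol(v))
  if (diff(rng) == 0) {
    q[fin] <- 1
  } else {
    brk <- seq(rng[1], rng[2], length.out = levels + 1)
    q[fin] <- findInterval(v[fin], brk, rightmost.closed = TRUE,
                           all.inside = TRUE)
  }
  q
}

#' Multicollinearity screening of continuous covariates
#'
#' Computes pairwise Pearson correlations on a random sample of
#' complete-case pixels and iteratively resolves pairs with |r| above the
#' threshold: from the strongest-correlated offending pair, the member
#' dropped is (in order of precedence) the one not protected by
#' `always_keep`; a texMean/texVar texture layer (these duplicate other
#' textural properties); otherwise the member with the larger mean
#' absolute correlation with all remaining layers. Protected layers are
#' never dropped — the land-cover pair is the intended use, retaining a
#' dynamic input even when the two epochs correlate strongly.
#'
#' @param stack a [covariate_stack()].
#' @param n_sample number of pixels sampled for the correlation matrix.
#' @param r_threshold absolute correlation above which a pair offends.
#' @param always_keep character vector of layer names never dropped.
#' @param seed integer seed for the pixel sample.
#' @return list with `retained` (layer names, categorical layers always
#'   retained), `dropped`, and `cor_matrix` (continuous layers, sampled
#'   pixels).
#' @export
screen_collinearity <- function(stack, n_sample = 5000, r_threshold = 0.8,
                                always_keep = character(0), seed = 1L) {
  cont <- names(stack$layers)[stack$kind_tags == "continuous"]
  if (!length(cont)) stop("no continuous layers to screen")
  vals <- sapply(cont, function(nm) as.vector(stack$layers[[nm]]$values))
  ok <- stats::complete.cases(vals)
  idx <- which(ok)
  if (length(idx) < 2) stop("not enough complete-case pixels")
  if (n_sample > length(idx)) {
    warning("n_sample exceeds valid pixels; using all ", length(idx))
    n_sample <- length(idx)
  }
  pick <- with_seed(seed, sample(idx, n_sample))
  cm <- stats::cor(vals[pick, , drop = FALSE])
  keep <- cont
  dropped <- character(0)
  repeat {
    sub <- abs(cm[keep, keep, drop = FALSE])
    diag(sub) <- 0
    # ignore conflicts between two protected layers
    prot <- keep %in% always_keep
    sub[prot, prot] <- 0
    if (all(sub <= r_threshold, na.rm = TRUE)) break
    pos <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- keep[pos[1]]; b <- keep[pos[2]]
    cand <- setdiff(c(a, b), always_keep)
    if (length(cand) == 2) {
      is_tex <- grepl("texMean|texVar", cand)
      if (sum(is_tex) == 1) {
        cand <- cand[is_tex]
      } else {
        mean_r <- vapply(cand, function(x)
          mean(abs(cm[x, setdiff(keep, x)])), numeric(1))
        cand <- cand[order(-mean_r, -match(cand, cont))][1]
      }
    }
    dropped <- c(dropped, cand[1])
    keep <- setdiff(keep, cand[1])
  }
  list(retained = c(keep, names(stack$layers)[stack$kind_tags == "categorical"]),
       dropped = dropped, cor_matrix = cm)
}

#' Extract covariates at plot locations into a design matrix
#'
#' Nearest-cell (point-in-cell) lookup of every stack layer at the plot
#' coordinates. Categorical layers are one-hot expanded (one indicator
#' column per class level, named `layer.level`). Plots falling on any
#' missing covariate cell are dropped and the count reported.
#'
#' @param stack a [covariate_stack()].
#' @param refset a [reference_set()].
#' @param retained optional character vector restricting the layers used
#'   (e.g. the result of [screen_collinearity()]).
#' @return object of class `design_matrix`: numeric matrix `X`, vectors
#'   `response`, `weights`, data.frame `coords`, plus the encoding needed
#'   to reproduce the expansion at prediction time.
#' @export
extract_at_plots <- function(stack, refset, retained = NULL) {
  nm <- if (is.null(retained)) names(stack$layers) else retained
  miss_l <- setdiff(nm, names(stack$layers))
  if (length(miss_l)) stop("missing covariate layer: ", paste(miss_l, collapse = ", "))
  rec <- refset$records
  raw <- sapply(nm, function(n)
    extract_cells(stack$layers[[n]], rec$x, rec$y))
  raw <- matrix(raw, nrow = nrow(rec), dimnames = list(NULL, nm))
  ok <- stats::complete.cases(raw)
  if (!any(ok)) stop("all plots fall outside the grid or on missing cells")
  if (any(!ok)) {
    message(sprintf("extract_at_plots: dropped %d plots on missing cells", sum(!ok)))
  }
  raw <- raw[ok, , drop = FALSE]
  rec <- rec[ok, , drop = FALSE]
  encoding <- list()
  cols <- list()
  for (n in nm) {
    if (stack$kind_tags[[n]] == "categorical") {
      lv <- stack$layers[[n]]$levels
      codes <- if (is.null(lv)) sort(unique(as.vector(stack$layers[[n]]$values)))
               else seq_along(lv)
      labs <- if (is.null(lv)) as.character(codes) else lv
      encoding[[n]] <- list(codes = codes, labels = labs)
      oh <- sapply(codes, function(cd) as.numeric(raw[, n] == cd))
      oh <- matrix(oh, nrow = nrow(raw),
                   dimnames = list(NULL, paste(n, labs, sep = ".")))
      cols[[n]] <- oh
    } else {
      cols[[n]] <- matrix(raw[, n], ncol = 1, dimnames = list(NULL, n))
    }
  }
  X <- do.call(cbind, cols)
  structure(list(
    X = X, response = rec$flux_obs, weights = rec$weight,
    coords = rec[, c("x", "y")], plot_id = rec$plot_id,
    covariates = nm, kind_tags = stack$kind_tags[nm],
    category_tags = stack$category_tags[nm], encoding = encoding,
    n_dropped = sum(!ok)
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d plots x %d columns (%d covariates)\n",
              nrow(x$X), ncol(x$X), length(x$covariates)))
  invisible(x)
}

# Expand stack pixels into the training column layout; rows with any
# missing covariate become all-NA. Returns a matrix with one row per cell.
stack_design_rows <- function(stack, design, cells = NULL) {
  nm <- design$covariates
  n_cell <- length(stack$layers[[1]]$values)
  if (is.null(cells)) cells <- seq_len(n_cell)
  cols <- list()
  for (n in nm) {
    v <- stack$layers[[n]]$values[cells]
    if (design$kind_tags[[n]] == "categorical") {
      enc <- design$encoding[[n]]
      oh <- sapply(enc$codes, function(cd) as.numeric(v == cd))
      oh <- matrix(oh, nrow = length(v),
                   dimnames = list(NULL, paste(n, enc$labels, sep = ".")))
      cols[[n]] <- oh
    } else {
      cols[[n]] <- matrix(v, ncol = 1, dimnames = list(NULL, n))
    }
  }
  X <- do.call(cbind, cols)
  X[!stats::complete.cases(X), ] <- NA_real_
  X
}
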