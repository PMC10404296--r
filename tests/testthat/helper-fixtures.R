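# Shared fixture builders; everything is generated in code at test time.

# Small reference set with explicit flags/variances.
make_refset <- function(flux = c(-10, 5, 0, 20, -3),
                        var = rep(NA_real_, length(flux)),
                        forest_change = rep(FALSE, length(flux)),
                        edge = rep(FALSE, length(flux)),
                        source = rep("NFI", length(flux)),
                        units = "carbon") {
  n <- length(flux)
  reference_set(data.frame(
    plot_id = sprintf("T%03d", seq_len(n)),
    x = seq(50, by = 100, length.out = n),
    y = rep(50, n),
    flux_obs = flux, flux_var = var, source = source,
    forest_change_flag = forest_change, edge_flag = edge,
    stringsAsFactors = FALSE
  ), design_tag = "uniform", units_note = units)
}

# Quick learner specs (single grid combination each) for fast fits.
quick_specs <- function() {
  list(
    learner_spec("bagged_trees", list(num_trees = 150, mtry_frac = NA)),
    learner_spec("gradient_boosted_trees",
                 list(nrounds = 100, max_depth = 3, eta = 0.1)),
    learner_spec("kernel_margin", list(cost = 1, bw_mult = 1))
  )
}

# Scenario -> prepared design matrix (weights filled), stack included.
make_design <- function(spec) {
  scn <- simulate_scenario(spec)
  refset <- suppressMessages(
    compute_case_weights(estimate_plot_variance(filter_plots(scn$plots))))
  stack <- covariate_stack(scn$covariates)
  list(scenario = scn, refset = refset, stack = stack,
       design = extract_at_plots(stack, refset))
}

# Literal double-loop GLCM oracle for one window (symmetric, pooled
# offsets, 1-based levels) — independent of the package implementation.
glcm_window_oracle <- function(win, gray_levels, rng) {
  if (diff(rng) == 0) {
    q <- matrix(1, nrow(win), ncol(win))
  } else {
    brk <- seq(rng[1], rng[2], length.out = gray_levels + 1)
    q <- matrix(findInterval(win, brk, rightmost.closed = TRUE,
                             all.inside = TRUE), nrow(win))
  }
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  counts <- matrix(0, gray_levels, gray_levels)
  for (off in offs) {
    for (r in seq_len(nrow(q))) {
      for (c in seq_len(ncol(q))) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
          counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
          counts[q[r2, c2], q[r, c]] <- counts[q[r2, c2], q[r, c]] + 1
        }
      }
    }
  }
  P <- counts / sum(counts)
  i <- row(P); j <- col(P)
  mu <- sum(i * P)
  list(texMean = mu, texVar = sum((i - mu)^2 * P),
       texHomo = sum(P / (1 + (i - j)^2)),
       texContrast = sum((i - j)^2 * P))
}

# Gaussian random field on scattered points from an exponential
# covariance model (Cholesky), for variogram recovery tests.
sim_exp_field <- function(n, domain, eff_range_m, psill, nugget, seed) {
  set.seed(seed)
  xy <- matrix(runif(2 * n, 0, domain), n, 2)
  D <- as.matrix(dist(xy))
  C <- psill * exp(-D / (eff_range_m / 3)) + diag(nugget, n)
  data.frame(x = xy[, 1], y = xy[, 2],
             residual = drop(t(chol(C)) %*% rnorm(n)))
}
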