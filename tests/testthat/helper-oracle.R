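# Independent oracles used to check the package's estimators. These
# deliberately share no code with the implementation paths they test.

# Brute-force least squares: exhaustive grid over (center, width) at
# `step` px resolution; for each grid point the plateau and background
# are profiled out by linear least squares and sigma by 1-D golden
# search. Returns the minimal residual sum of squares found.
grid_rss_oracle <- function(profile, c_range, w_range, step = 0.1,
                            sigma_bounds = c(0.1, 10)) {
  x <- seq_along(profile) - 0.5
  rss_cws <- function(cc, ww, s) {
    S <- pnorm((x - cc + ww / 2) / s) - pnorm((x - cc - ww / 2) / s)
    r <- stats::lm.fit(cbind(S, 1), profile)$residuals
    sum(r^2)
  }
  best <- Inf
  for (cc in seq(c_range[1], c_range[2], by = step)) {
    for (ww in seq(w_range[1], w_range[2], by = step)) {
      v <- stats::optimize(function(s) rss_cws(cc, ww, s),
                           sigma_bounds, tol = 1e-6)$objective
      if (v < best) best <- v
    }
  }
  best
}

# Closed-form simple-regression solution from raw sums.
ols_closed_form <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Type-7 empirical quantile computed directly from the order statistics.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# Small, fast condition config for module-level tests (not the study
# conditions; those live in test-acceptance.R).
tiny_config <- function(...) {
  args <- utils::modifyList(list(fov_length_px = 96L,
                                 frames_per_molecule = 40L,
                                 condition_label = "tiny"),
                            list(...))
  do.call(sim_config, args)
}

# Two-sample population like the pooled experimental samples: n at each
# of two dye:bp ratios under one condition, unique molecule ids.
pooled_population <- function(config, n_each, ratios = c(1 / 20, 1 / 5),
                              heterogeneity = 1.5, seed = 1L) {
  pops <- lapply(seq_along(ratios), function(k) {
    p <- simulate_population(config, n_each, ratios[k],
                             heterogeneity = heterogeneity,
                             seed = seed + 1000L * k)
    p$truth$molecule_id <- sprintf("s%d_%s", k, p$truth$molecule_id)
    p
  })
  out <- pops[[1]]
  out$truth <- do.call(rbind, lapply(pops, `[[`, "truth"))
  rownames(out$truth) <- NULL
  out
}
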