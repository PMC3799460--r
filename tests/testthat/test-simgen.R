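test_that("dye loads honor stoichiometry, spread and range contracts", {
  # zero-heterogeneity limit: forced arithmetic, 4 bp/dye * 0.2 dye/bp
  expect_identical(sample_dye_loads(5, 1 / 5, heterogeneity = 0),
                   rep(0.8, 5))

  # Monte-Carlo conservation of total dye at 1:40
  th <- sample_dye_loads(10000, 1 / 40, heterogeneity = 2, seed = 1)
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - 0.1), 3 * se)
  expect_true(all(th >= 0 & th <= 1))

  # single draw stays in range
  one <- sample_dye_loads(1, 1 / 10, heterogeneity = 5, seed = 2)
  expect_length(one, 1)
  expect_true(one >= 0 && one <= 1)

  # variance grows with heterogeneity
  v <- vapply(c(0.5, 1, 2, 4), function(h)
    var(sample_dye_loads(5000, 1 / 10, h, seed = 3)), numeric(1))
  expect_true(all(diff(v) > 0))

  # above-saturation request names the limit
  expect_error(sample_dye_loads(10, 0.3, 1), "1 dye per 4 bp")
})

test_that("dye equilibration conserves total dye and narrows monotonically", {
  expect_identical(equilibrate_dye(c(0.2, 0.8), 0, 24), c(0.2, 0.8))
  expect_equal(equilibrate_dye(c(0.2, 0.8), 1e3, 1e3), c(0.5, 0.5))

  loads <- sample_dye_loads(1000, 1 / 40, 2, seed = 4)
  relaxed <- lapply(c(0, 3, 24), function(d) equilibrate_dye(loads, 0.3, d))
  vars <- vapply(relaxed, var, numeric(1))
  expect_true(all(diff(vars) < 0))
  for (r in relaxed)
    expect_lt(abs(mean(r) - mean(loads)) / mean(loads), 1e-12)

  # conservation holds across rates and durations, with and without
  # exchange noise
  for (rate in c(0, 0.1, 2)) for (d in c(0.5, 10)) {
    out <- equilibrate_dye(loads, rate, d)
    expect_lt(abs(mean(out) - mean(loads)) / mean(loads), 1e-12)
    noisy <- equilibrate_dye(loads, rate, d, seed = 5, exchange_sd = 0.02)
    expect_lt(abs(mean(noisy) - mean(loads)) / mean(loads), 1e-12)
    expect_true(all(noisy >= 0 & noisy <= 1))
  }

  expect_error(equilibrate_dye(c(0.5), -1, 1))
  expect_error(equilibrate_dye(c(0.5), 1, -1))
})

test_that("extension law is affine with the stated slope and intercept", {
  cfg <- sim_config(native_extension_um = 10)
  expect_equal(true_extension(0, cfg), 10.0)
  expect_equal(true_extension(1, cfg), 13.75)     # 0.51/1.36 = 0.375
  expect_equal(true_extension(0.5, cfg), 11.875)  # midway: affine

  th <- seq(0, 1, by = 0.05)
  w <- true_extension(th, cfg)
  co <- ols_closed_form(th, w)
  expect_equal(unname(co["intercept"]), cfg$native_extension_um,
               tolerance = 1e-12)
  expect_equal(unname(co["slope"]) / unname(co["intercept"]),
               cfg$dye_extension_nm / (cfg$dye_site_bp * cfg$rise_per_bp_nm),
               tolerance = 1e-12)
  expect_true(all(diff(w) > 0))
  expect_error(true_extension(1.2, cfg), "saturation")
})

test_that("rendered frames obey the box limit, conservation and determinism", {
  cfg <- tiny_config(psf_sigma_px = 0.01)
  tr <- molecule_truth(0.5, cfg)
  fr <- render_frame(tr, center_um = 7.68, config = cfg, noise = FALSE)
  prof <- colSums(fr)
  b_tot <- cfg$fov_height_px * cfg$background_level
  px <- cfg$pixel_size_um
  c_px <- 7.68 / px
  w_px <- tr$mean_extension_um / px
  x <- seq_len(cfg$fov_length_px) - 0.5
  inside <- x > c_px - w_px / 2 + 0.6 & x < c_px + w_px / 2 - 0.6
  outside <- x < c_px - w_px / 2 - 0.6 | x > c_px + w_px / 2 + 0.6
  expect_equal(prof[inside], rep(b_tot + tr$plateau_amplitude, sum(inside)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(prof[outside], rep(b_tot, sum(outside)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # integrated-signal conservation under blur, sigma <= w/4
  for (sig in c(0.5, 2, 6)) {
    cfg2 <- tiny_config(psf_sigma_px = sig)
    tr2 <- molecule_truth(0.6, cfg2)
    stopifnot(sig <= tr2$mean_extension_um / cfg2$pixel_size_um / 4)
    fr2 <- render_frame(tr2, 7.68, cfg2, noise = FALSE)
    integ <- sum(colSums(fr2) - cfg2$fov_height_px * cfg2$background_level) *
      cfg2$pixel_size_um
    expect_lt(abs(integ / (tr2$plateau_amplitude * tr2$mean_extension_um) - 1),
              0.01)
  }

  # seeded determinism
  cfg3 <- tiny_config()
  tr3 <- molecule_truth(0.4, cfg3)
  f1 <- render_frame(tr3, 7.68, cfg3, seed = 11)
  f2 <- render_frame(tr3, 7.68, cfg3, seed = 11)
  expect_identical(f1, f2)

  # molecule overflowing the field of view is rejected
  cfg4 <- tiny_config(fov_length_px = 32L)
  tr4 <- molecule_truth(1, cfg4)
  expect_error(render_frame(tr4, 2.56, cfg4), "field too small")
})

test_that("noisy rendering matches the noiseless expectation in the mean", {
  cfg <- tiny_config(fov_length_px = 32L, fov_height_px = 5L,
                     native_extension_um = 1.2)
  tr <- molecule_truth(0.3, cfg)
  lam <- render_frame(tr, 2.56, cfg, noise = FALSE)
  n_draw <- 12000
  acc <- matrix(0, nrow(lam), ncol(lam))
  acc2 <- matrix(0, nrow(lam), ncol(lam))
  for (i in seq_len(n_draw)) {
    f <- render_frame(tr, 2.56, cfg, seed = 100000 + i)
    acc <- acc + f
    acc2 <- acc2 + f^2
  }
  mu <- acc / n_draw
  se <- sqrt(pmax(acc2 / n_draw - mu^2, 1e-12) / n_draw)
  # zero-clipping shifts the mean of low-count pixels up; the closed-form
  # expectation of the clipped count is
  #   lambda + sum_k P(Pois(lambda) = k) * (s*phi(k/s) - k*Phi(-k/s))
  clipped_mean <- function(lam, s) {
    ks <- 0:max(30, ceiling(lam + 10 * sqrt(lam)))
    lam + sum(dpois(ks, lam) * (s * dnorm(ks / s) - ks * pnorm(-ks / s)))
  }
  expec <- matrix(vapply(lam, clipped_mean, numeric(1),
                         s = cfg$read_noise_sd), nrow(lam), ncol(lam))
  z <- abs(mu - expec) / se
  # max over ~160 pixels: multiplicity-adjusted threshold
  expect_lt(max(z), 4.5)
})

test_that("stacks follow the configured extension and centre dynamics", {
  frozen <- tiny_config(extension_fluct_sd_um = 0,
                        center_diffusion_step_um = 0)
  tr <- molecule_truth(0.5, frozen)
  st <- render_stack(tr, frozen, seed = 1, noise = FALSE)
  expect_length(st$frames, frozen$frames_per_molecule)
  for (f in st$frames) expect_identical(f, st$frames[[1]])

  cfg <- sim_config(extension_fluct_sd_um = 0.2)
  tr2 <- molecule_truth(0.5, cfg)
  st2 <- render_stack(tr2, cfg, seed = 21)
  # sample sd of the AR(1) truth vs stationary sd, with the effective
  # sample size reduced by the lag-one correlation
  n_eff <- cfg$frames_per_molecule * (1 - cfg$ext_ar1_phi) /
    (1 + cfg$ext_ar1_phi)
  se_sd <- 0.2 / sqrt(2 * n_eff)
  expect_lt(abs(sd(st2$extensions_um) - 0.2), 3 * se_sd)

  expect_identical(st2$pixel_size_um, cfg$pixel_size_um)
  expect_identical(st2$exposure_s, cfg$exposure_s)
  expect_identical(st2$truth, tr2)

  # same seed, same stack
  st3 <- render_stack(tr2, cfg, seed = 21)
  expect_identical(st2$frames, st3$frames)
})
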