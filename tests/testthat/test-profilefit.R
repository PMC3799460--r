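test_that("kymograph extraction is exact transverse summation", {
  cfg <- tiny_config(extension_fluct_sd_um = 0,
                     center_diffusion_step_um = 0)
  tr <- molecule_truth(0.5, cfg)
  st <- render_stack(tr, cfg, seed = 1, noise = FALSE)
  ky <- extract_kymograph(st)
  for (t in seq_len(nrow(ky$rows)))
    expect_equal(ky$rows[t, ], ky$rows[1, ], ignore_attr = TRUE)

  zero <- structure(list(frames = list(matrix(0, 4, 20), matrix(0, 4, 20)),
                         pixel_size_um = 0.16, exposure_s = 0.1,
                         truth = NULL), class = "image_stack")
  expect_true(all(extract_kymograph(zero)$rows == 0))

  # tiny printed array vs hand-computed column sums
  set.seed(9)
  frames <- lapply(1:3, function(i) matrix(sample(0:9, 24, TRUE), 4, 6))
  stack <- structure(list(frames = frames, pixel_size_um = 0.1,
                          exposure_s = 0.1, truth = NULL),
                     class = "image_stack")
  ky2 <- extract_kymograph(stack)
  for (t in 1:3) for (j in 1:6) {
    s <- 0
    for (i in 1:4) s <- s + frames[[t]][i, j]
    expect_identical(ky2$rows[t, j], s)
  }

  empty <- structure(list(frames = list(), pixel_size_um = 0.1,
                          exposure_s = 0.1), class = "image_stack")
  expect_error(extract_kymograph(empty), "empty")
})

test_that("the box-erf fit recovers noiseless model profiles exactly", {
  x <- seq_len(64) - 0.5
  y <- box_erf_profile(x, center = 32, width = 16, plateau = 100,
                       background = 5, sigma = 2)
  f <- fit_frame(y, pixel_size_um = 1)
  expect_true(f$valid)
  expect_lt(abs(f$center_um - 32), 1e-3)
  expect_lt(abs(f$extension_um - 16), 1e-3)
  expect_equal(f$integrated_intensity, f$plateau * f$extension_um)

  # property: exact recovery across a (w, sigma, A/b) grid
  for (w in c(8, 16, 40)) for (sig in c(0.5, 2, 4)) for (snr in c(5, 100)) {
    b <- 5; A <- snr * b
    yy <- box_erf_profile(seq_len(96) - 0.5, 48, w, A, b, sig)
    ff <- fit_frame(yy, 1)
    expect_true(ff$valid)
    expect_lt(abs(ff$center_um - 48), 1e-3)
    expect_lt(abs(ff$extension_um - w), 1e-3)
  }
})

test_that("degenerate profiles are flagged invalid, never errors", {
  flat <- rep(5, 64)
  f <- fit_frame(flat, 1)
  expect_false(f$valid)
  expect_match(f$reason, "no signal")

  noise_only <- 5 + rnorm(64, sd = 2)
  expect_false(fit_frame(abs(noise_only), 1)$valid)

  expect_error(fit_frame(rep(1, 10), 1), "16 pixels")
  expect_error(fit_frame(c(rep(1, 63), NA), 1), "non-finite")
})

test_that("the fit matches the brute-force grid-search oracle on noisy data", {
  set.seed(31)
  truth <- list(c = 30.7, w = 17.3, A = 80, b = 6, s = 1.4)
  y <- rpois(64, box_erf_profile(seq_len(64) - 0.5, truth$c, truth$w,
                                 truth$A, truth$b, truth$s))
  f <- fit_frame(y, 1)
  expect_true(f$valid)
  oracle <- grid_rss_oracle(y, truth$c + c(-3, 3), truth$w + c(-3, 3))
  expect_lte(f$residual_ss, oracle + 1e-6)
  # grid resolution is 0.1 px; the continuous fit should sit within it
  expect_lt(abs(f$center_um - truth$c), 1)
  expect_lt(abs(f$extension_um - truth$w), 1.5)
})

test_that("fitted extension statistics agree with the generating process", {
  cfg <- sim_config()
  tr <- molecule_truth(0.5, cfg)
  st <- render_stack(tr, cfg, seed = 8)
  fits <- fit_kymograph(extract_kymograph(st))
  expect_true(all(fits$valid))
  n_eff <- cfg$frames_per_molecule * (1 - cfg$ext_ar1_phi) /
    (1 + cfg$ext_ar1_phi)
  se_mean <- cfg$extension_fluct_sd_um / sqrt(n_eff)
  expect_lt(abs(mean(fits$extension_um) - tr$mean_extension_um), 3 * se_mean)
  se_sd <- cfg$extension_fluct_sd_um / sqrt(2 * n_eff)
  expect_lt(abs(sd(fits$extension_um) - cfg$extension_fluct_sd_um),
            3 * se_sd)
})

test_that("alignment centres the molecule and is idempotent", {
  cfg <- tiny_config(extension_fluct_sd_um = 0, center_diffusion_step_um = 0,
                     frames_per_molecule = 21L)
  tr <- molecule_truth(0.5, cfg)
  px <- cfg$pixel_size_um
  # drifting +1 px per frame, noiseless; odd frame count keeps the median
  # centre on the pixel grid so integer-shift alignment is exact
  centers <- (30 + seq_len(21)) * px
  rows <- t(vapply(centers, function(cc)
    colSums(render_frame(tr, cc, cfg, noise = FALSE)),
    numeric(cfg$fov_length_px)))
  ky <- structure(list(rows = rows, pixel_size_um = px,
                       frame_interval_s = 0.1), class = "kymograph")
  fits <- fit_kymograph(ky)
  expect_true(all(fits$valid))
  al <- align_kymograph(ky, fits)
  for (t in seq_len(21))
    expect_equal(al$rows[t, ], al$rows[1, ], tolerance = 1e-8,
                 ignore_attr = TRUE)

  # identical centres: no-op
  same <- structure(list(rows = rows[rep(1, 5), ], pixel_size_um = px,
                         frame_interval_s = 0.1), class = "kymograph")
  fits_same <- fit_kymograph(same)
  expect_equal(align_kymograph(same, fits_same)$rows, same$rows)

  # idempotence
  fits_al <- fit_kymograph(al)
  al2 <- align_kymograph(al, fits_al)
  expect_equal(al2$rows, al$rows)

  # all-invalid input passes through with a warning
  flat <- structure(list(rows = matrix(5, 4, 64), pixel_size_um = px,
                         frame_interval_s = 0.1), class = "kymograph")
  fits_flat <- fit_kymograph(flat)
  expect_warning(out <- align_kymograph(flat, fits_flat), "no valid")
  expect_equal(out$rows, flat$rows)

  expect_error(align_kymograph(ky, fits[1:3, ]), "mismatch")
})

test_that("molecule summaries average valid frames only", {
  one <- data.frame(extension_um = 14, integrated_intensity = 1000,
                    valid = TRUE)
  s <- summarize_molecule(one[rep(1, 200), ])
  expect_equal(s$mean_extension_um, 14)
  expect_equal(s$extension_sd_um, 0)
  expect_equal(s$n_valid_frames, 200)
  expect_true(s$valid)

  three <- data.frame(extension_um = c(10, 12, 14),
                      integrated_intensity = c(1, 2, 3),
                      valid = TRUE)
  s3 <- summarize_molecule(three)
  expect_equal(s3$mean_extension_um, 12)
  expect_equal(s3$extension_sd_um, 2)

  mixed <- data.frame(extension_um = c(rep(10, 40), rep(99, 160)),
                      integrated_intensity = 1,
                      valid = c(rep(TRUE, 40), rep(FALSE, 160)))
  sm <- summarize_molecule(mixed, min_valid_fraction = 0.5)
  expect_false(sm$valid)
  expect_equal(sm$n_valid_frames, 40)
  expect_equal(sm$mean_extension_um, 10)  # invalid frames excluded
})
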