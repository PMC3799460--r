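#' Simulation configuration for a nanochannel imaging condition
#'
#' Bundles the molecular constants, optics, camera and dynamics parameters
#' that define one simulated experimental condition (one buffer / ionic
#' strength). Defaults describe lambda-phage DNA (48.5 kb) imaged at 100 ms
#' exposure, 200 frames per molecule, on a camera with 0.16 um pixels.
#'
#' The extension model is affine in the dye saturation \eqn{\theta}
#' (fraction of the one-dye-per-`dye_site_bp` maximum):
#' \deqn{w(\theta) = w_0 \left(1 + \theta\,
#'   \frac{\delta}{s\,r}\right)}
#' with \eqn{w_0} = `native_extension_um`, \eqn{\delta} = `dye_extension_nm`
#' (contour added per bound dye), \eqn{s} = `dye_site_bp` and \eqn{r} =
#' `rise_per_bp_nm` (0.34 nm for B-DNA). With the defaults the relative
#' increase at saturation is 0.51/1.36 = 37.5%. `dye_extension_nm` is the
#' *effective* per-dye extension gain of the condition; lowering it mimics
#' the weaker extension response observed at high ionic strength.
#'
#' @param native_extension_um mean extension of dye-free DNA in this
#'   condition (um). Roughly doubles from high (5x TBE) to very low
#'   (0.05x TBE) ionic strength for lambda-DNA in a 100x150 nm channel.
#' @param genome_size_bp molecule size in basepairs.
#' @param rise_per_bp_nm helical rise per basepair (nm).
#' @param dye_site_bp basepairs occluded per dye at saturation
#'   (nearest-neighbour exclusion: 4).
#' @param dye_extension_nm contour length added per bound dye (nm).
#' @param pixel_size_um camera pixel size in the sample plane (um).
#' @param psf_sigma_px Gaussian point-spread-function sigma in pixels.
#' @param fov_length_px,fov_height_px field-of-view size along / across
#'   the channel, pixels.
#' @param frames_per_molecule frames recorded per molecule.
#' @param exposure_s exposure time per frame (s).
#' @param amplitude_at_saturation plateau amplitude (photons per
#'   along-channel pixel column, after transverse summation) of a fully
#'   saturated molecule at its full extension. Sets the signal-to-noise
#'   scale and thereby the detection limit.
#' @param background_level mean background, photons per pixel per frame.
#' @param read_noise_sd camera read noise, photons (Gaussian sd) per pixel.
#' @param extension_fluct_sd_um stationary sd of the per-frame extension
#'   fluctuation around the molecule mean (um).
#' @param ext_ar1_phi lag-one autocorrelation of the extension fluctuation.
#' @param center_diffusion_step_um sd of the per-frame centre-of-mass step
#'   (um); the centre performs a reflected random walk.
#' @param extension_scatter_um molecule-to-molecule sd of the mean
#'   extension around the extension law (um), e.g. channel-to-channel
#'   variation.
#' @param condition_label free-text label carried into outputs.
#' @return object of class `sim_config` (a validated list).
#' @seealso [true_extension()], [render_stack()], [simulate_population()]
#' @export
sim_config <- function(native_extension_um = 5.0,
                       genome_size_bp = 48500L,
                       rise_per_bp_nm = 0.34,
                       dye_site_bp = 4L,
                       dye_extension_nm = 0.51,
                       pixel_size_um = 0.16,
                       psf_sigma_px = 1.0,
                       fov_length_px = 160L,
                       fov_height_px = 7L,
                       frames_per_molecule = 200L,
                       exposure_s = 0.1,
                       amplitude_at_saturation = 400,
                       background_level = 4,
                       read_noise_sd = 2,
                       extension_fluct_sd_um = 0.3,
                       ext_ar1_phi = 0.5,
                       center_diffusion_step_um = 0.05,
                       extension_scatter_um = 0.15,
                       condition_label = "default") {
  cfg <- list(
    native_extension_um = native_extension_um,
    genome_size_bp = as.integer(genome_size_bp),
    rise_per_bp_nm = rise_per_bp_nm,
    dye_site_bp = as.integer(dye_site_bp),
    dye_extension_nm = dye_extension_nm,
    pixel_size_um = pixel_size_um,
    psf_sigma_px = psf_sigma_px,
    fov_length_px = as.integer(fov_length_px),
    fov_height_px = as.integer(fov_height_px),
    frames_per_molecule = as.integer(frames_per_molecule),
    exposure_s = exposure_s,
    amplitude_at_saturation = amplitude_at_saturation,
    background_level = background_level,
    read_noise_sd = read_noise_sd,
    extension_fluct_sd_um = extension_fluct_sd_um,
    ext_ar1_phi = ext_ar1_phi,
    center_diffusion_step_um = center_diffusion_step_um,
    extension_scatter_um = extension_scatter_um,
    condition_label = as.character(condition_label)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (genome_size_bp <= 0L) stop("genome_size_bp must be > 0", call. = FALSE)
    if (dye_site_bp < 1L) stop("dye_site_bp must be >= 1", call. = FALSE)
    if (frames_per_molecule < 1L)
      stop("frames_per_molecule must be >= 1", call. = FALSE)
    lens <- c(native_extension_um, rise_per_bp_nm, dye_extension_nm,
              pixel_size_um, psf_sigma_px, exposure_s)
    if (any(!is.finite(lens)) || any(lens <= 0))
      stop("all lengths and times must be positive and finite", call. = FALSE)
    if (background_level < 0 || read_noise_sd < 0 ||
        extension_fluct_sd_um < 0 || center_diffusion_step_um < 0 ||
        extension_scatter_um < 0)
      stop("noise and fluctuation parameters must be >= 0", call. = FALSE)
    if (ext_ar1_phi < 0 || ext_ar1_phi >= 1)
      stop("ext_ar1_phi must be in [0, 1)", call. = FALSE)
    if (fov_length_px < 16L || fov_height_px < 1L)
      stop("field of view too small", call. = FALSE)
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> condition:", x$condition_label, "\n")
  cat(sprintf("  native extension %.2f um; +%.2f nm per dye (1 per %d bp, rise %.2f nm/bp)\n",
              x$native_extension_um, x$dye_extension_nm, x$dye_site_bp,
              x$rise_per_bp_nm))
  cat(sprintf("  %d frames x %.0f ms, %dx%d px FOV @ %.3f um/px, PSF sigma %.2f px\n",
              x$frames_per_molecule, 1000 * x$exposure_s, x$fov_height_px,
              x$fov_length_px, x$pixel_size_um, x$psf_sigma_px))
  invisible(x)
}

#' Mean extension of a molecule at a given dye saturation
#'
#' The affine extension law: intercalation adds `dye_extension_nm` of
#' contour per bound dye, and the confined extension scales with contour
#' length, so
#' `native_extension_um * (1 + saturation * dye_extension_nm /
#' (dye_site_bp * rise_per_bp_nm))`.
#'
#' @param saturation dye saturation \eqn{\theta} in \[0, 1\] (fraction of
#'   the one-dye-per-4-bp maximum); vectorised.
#' @param config a [sim_config()].
#' @return mean extension(s) in um, strictly increasing in `saturation`.
#' @examples
#' cfg <- sim_config(native_extension_um = 10)
#' true_extension(c(0, 0.5, 1), cfg)  # 10, 11.875, 13.75
#' @export
true_extension <- function(saturation, config) {
  validate_sim_config(config)
  if (any(!is.finite(saturation)) || any(saturation < 0 | saturation > 1))
    stop("saturation must lie in [0, 1]", call. = FALSE)
  rel <- config$dye_extension_nm / (config$dye_site_bp * config$rise_per_bp_nm)
  config$native_extension_um * (1 + saturation * rel)
}

#' Draw per-molecule dye saturations for a freshly mixed sample
#'
#' Staining at substoichiometric dye:bp ratios is heterogeneous: molecules
#' in one tube carry very different amounts of dye, with a continuous
#' (single-mode, not two-population) distribution. Saturations are drawn
#' from a Beta distribution whose mean is fixed by the sample stoichiometry
#' (`dye_site_bp * mean_dye_per_bp`, conserving total dye on average) and
#' whose spread grows with `heterogeneity`: the Beta concentration is
#' `1/heterogeneity`, so variance `= mu(1-mu) * h/(1+h)` increases
#' monotonically in `h`. `heterogeneity = 0` is the fully equilibrated
#' limit where every molecule carries exactly the mean load.
#'
#' @param n_molecules number of molecules to draw.
#' @param mean_dye_per_bp sample-average bound dye per basepair (e.g.
#'   1/40 for a dye:bp ratio of 1:40). Must not exceed `1/dye_site_bp`,
#'   the nearest-neighbour-exclusion saturation.
#' @param heterogeneity spread parameter >= 0 (dimensionless).
#' @param seed optional RNG seed for reproducibility.
#' @param dye_site_bp basepairs per dye at saturation (default 4).
#' @return numeric vector of `n_molecules` saturations in \[0, 1\].
#' @examples
#' sample_dye_loads(5, 1 / 5, heterogeneity = 0)    # all exactly 0.8
#' sample_dye_loads(10, 1 / 40, heterogeneity = 2, seed = 1)
#' @export
sample_dye_loads <- function(n_molecules, mean_dye_per_bp, heterogeneity,
                             seed = NULL, dye_site_bp = 4L) {
  if (n_molecules < 1L) stop("n_molecules must be >= 1", call. = FALSE)
  if (!is.finite(mean_dye_per_bp) || mean_dye_per_bp <= 0)
    stop("mean_dye_per_bp must be > 0", call. = FALSE)
  if (mean_dye_per_bp > 1 / dye_site_bp)
    stop(sprintf(paste0("mean_dye_per_bp = %.4g exceeds the intercalation ",
                        "saturation of 1 dye per %d bp (max %.4g dye/bp)"),
                 mean_dye_per_bp, dye_site_bp, 1 / dye_site_bp),
         call. = FALSE)
  if (!is.finite(heterogeneity) || heterogeneity < 0)
    stop("heterogeneity must be >= 0", call. = FALSE)
  mu <- dye_site_bp * mean_dye_per_bp
  if (heterogeneity == 0) return(rep(mu, n_molecules))
  kappa <- 1 / heterogeneity
  with_seed(seed, stats::rbeta(n_molecules, mu * kappa, (1 - mu) * kappa))
}

#' Relax a heterogeneous dye distribution toward equilibrium
#'
#' Dye redistribution between molecules (via dissociation and rebinding)
#' is modelled as first-order relaxation of each molecule's saturation
#' toward the cohort mean: `theta_i(t) = m + (theta_i(0) - m) *
#' exp(-relaxation_rate * duration)`. Total dye (the cohort mean) is
#' conserved exactly; variance shrinks monotonically with both rate and
#' duration, emulating the narrowing of intensity distributions with
#' heating time. The rate is a free parameter standing in for the
#' (unmodelled) ionic-strength- and temperature-dependent dissociation
#' kinetics: pass a larger rate for hotter or saltier conditions.
#'
#' Optionally, zero-mean Gaussian "exchange noise" of sd `exchange_sd` is
#' added and then re-centred (iteratively, with clipping to \[0, 1\]) so
#' conservation still holds to machine precision.
#'
#' @param loads saturations in \[0, 1\].
#' @param relaxation_rate relaxation rate, per hour (>= 0).
#' @param duration heating / waiting time, hours (>= 0).
#' @param seed optional RNG seed (used only when `exchange_sd > 0`).
#' @param exchange_sd sd of the optional exchange noise (default 0,
#'   deterministic relaxation).
#' @return relaxed saturations, same length and same mean as `loads`.
#' @examples
#' equilibrate_dye(c(0.2, 0.8), relaxation_rate = 0, duration = 24)
#' equilibrate_dye(c(0.2, 0.8), relaxation_rate = 100, duration = 100)
#' @export
equilibrate_dye <- function(loads, relaxation_rate, duration, seed = NULL,
                            exchange_sd = 0) {
  if (any(!is.finite(loads)) || any(loads < 0 | loads > 1))
    stop("loads must lie in [0, 1]", call. = FALSE)
  if (!is.finite(relaxation_rate) || relaxation_rate < 0)
    stop("relaxation_rate must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration < 0)
    stop("duration must be >= 0", call. = FALSE)
  m <- mean(loads)
  shrink <- exp(-relaxation_rate * duration)
  out <- m + (loads - m) * shrink
  if (exchange_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(loads), 0, exchange_sd))
    out <- out + noise - mean(noise)
    # alternate clipping to [0, 1] and re-centring until the mean is
    # restored to machine precision, ending on a clip
    for (i in seq_len(200)) {
      out <- pmin(1, pmax(0, out))
      delta <- m - mean(out)
      if (abs(delta) < 1e-16) break
      out <- out + delta
    }
    out <- pmin(1, pmax(0, out))
  }
  out
}

#' Per-molecule simulation ground truth
#'
#' Derives a molecule's rendering parameters from its dye saturation and
#' a condition config. The plateau amplitude is set so that the
#' *integrated* intensity (plateau x extension) is proportional to the
#' number of bound dyes, i.e. to `saturation`: total emission is assumed
#' linear in bound dye, so `plateau = amplitude_at_saturation *
#' saturation * w(1) / w(saturation)`.
#'
#' @param saturation dye saturation in \[0, 1\].
#' @param config a [sim_config()].
#' @param extension_offset_um additive offset on the mean extension
#'   (molecule-level scatter; drawn by [simulate_population()]).
#' @return object of class `molecule_truth`: list with `saturation`,
#'   `mean_extension_um`, `plateau_amplitude`, `extension_fluct_sd_um`,
#'   `center_diffusion_step_um`.
#' @export
molecule_truth <- function(saturation, config, extension_offset_um = 0) {
  validate_sim_config(config)
  if (length(saturation) != 1L || !is.finite(saturation) ||
      saturation < 0 || saturation > 1)
    stop("saturation must be a single value in [0, 1]", call. = FALSE)
  w <- true_extension(saturation, config) + extension_offset_um
  w_sat <- true_extension(1, config)
  plateau <- if (saturation == 0) 0 else
    config$amplitude_at_saturation * saturation * w_sat / w
  tr <- list(saturation = saturation,
             mean_extension_um = w,
             plateau_amplitude = plateau,
             extension_fluct_sd_um = config$extension_fluct_sd_um,
             center_diffusion_step_um = config$center_diffusion_step_um)
  class(tr) <- "molecule_truth"
  tr
}

# Transverse intensity weights: Gaussian profile across the channel,
# normalised to sum to 1 so the transverse sum recovers the 1D profile.
transverse_weights <- function(config) {
  h <- config$fov_height_px
  r <- seq_len(h) - 0.5
  wts <- stats::dnorm(r, mean = h / 2, sd = max(config$psf_sigma_px, 0.3))
  wts / sum(wts)
}

# Margin (px) required between the blurred molecule edge and the FOV edge.
fov_margin_px <- function(config) 3 + 3 * config$psf_sigma_px

check_fits_fov <- function(center_um, width_um, config) {
  px <- config$pixel_size_um
  lo <- (center_um - width_um / 2) / px
  hi <- (center_um + width_um / 2) / px
  m <- fov_margin_px(config)
  if (lo < m || hi > config$fov_length_px - m)
    stop(sprintf(paste0("field too small: molecule spans %.1f-%.1f px but ",
                        "needs a %.1f px margin inside [0, %d]"),
                 lo, hi, m, config$fov_length_px), call. = FALSE)
  invisible(TRUE)
}

#' Render one synthetic camera frame of a confined molecule
#'
#' The noiseless expectation of the transversely summed profile is the
#' [box_erf_profile()]: background plus plateau times the difference of
#' Gaussian CDFs at the two molecule edges. Signal is distributed over
#' transverse rows with a normalised Gaussian weight; each pixel receives
#' Poisson shot noise around its expectation plus Gaussian read noise,
#' clipped at zero.
#'
#' @param truth a [molecule_truth()].
#' @param center_um molecule centre position along the channel (um).
#' @param config a [sim_config()].
#' @param seed optional RNG seed (same seed, same frame, bit for bit).
#' @param noise logical; `FALSE` returns the noiseless expectation.
#' @param extension_um override of the frame extension (um); defaults to
#'   the truth mean.
#' @return `fov_height_px` x `fov_length_px` matrix of photon counts.
#' @export
render_frame <- function(truth, center_um, config, seed = NULL,
                         noise = TRUE, extension_um = NULL) {
  stopifnot(inherits(truth, "molecule_truth"))
  validate_sim_config(config)
  w_um <- if (is.null(extension_um)) truth$mean_extension_um else extension_um
  check_fits_fov(center_um, w_um, config)
  px <- config$pixel_size_um
  x <- seq_len(config$fov_length_px) - 0.5
  s <- box_erf_profile(x, center_um / px, w_um / px, 1, 0,
                       config$psf_sigma_px)
  lam <- config$background_level +
    outer(transverse_weights(config), truth$plateau_amplitude * s)
  if (!noise) return(lam)
  with_seed(seed, {
    counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam)) +
      stats::rnorm(length(lam), 0, config$read_noise_sd)
    pmax(counts, 0)
  })
}

#' Render a full image stack (time series) for one molecule
#'
#' The molecule centre performs a reflected Gaussian random walk with
#' per-frame step `center_diffusion_step_um`; the extension follows a
#' stationary AR(1) process with mean `mean_extension_um`, stationary sd
#' `extension_fluct_sd_um` and lag-one correlation `ext_ar1_phi`,
#' emulating the slow breathing of a confined chain between frames.
#'
#' @inheritParams render_frame
#' @return object of class `image_stack`: list with `frames` (list of
#'   count matrices), `pixel_size_um`, `exposure_s`, `truth`, and the
#'   per-frame ground-truth `centers_um` / `extensions_um`.
#' @export
render_stack <- function(truth, config, seed = NULL, noise = TRUE) {
  stopifnot(inherits(truth, "molecule_truth"))
  validate_sim_config(config)
  n <- config$frames_per_molecule
  px <- config$pixel_size_um
  check_fits_fov(config$fov_length_px * px / 2, truth$mean_extension_um +
                   6 * truth$extension_fluct_sd_um, config)
  with_seed(seed, {
    # extension AR(1), started from the stationary distribution
    phi <- config$ext_ar1_phi
    sd_stat <- truth$extension_fluct_sd_um
    eps_sd <- sd_stat * sqrt(1 - phi^2)
    dev <- numeric(n)
    dev[1] <- stats::rnorm(1, 0, sd_stat)
    if (n > 1)
      for (t in 2:n) dev[t] <- phi * dev[t - 1] + stats::rnorm(1, 0, eps_sd)
    ext <- pmax(truth$mean_extension_um + dev, 2 * px)

    # reflected random walk of the centre within the allowed span
    m_um <- fov_margin_px(config) * px
    half <- max(ext) / 2
    lo <- m_um + half
    hi <- config$fov_length_px * px - m_um - half
    ctr <- numeric(n)
    ctr[1] <- config$fov_length_px * px / 2
    if (n > 1) {
      steps <- stats::rnorm(n - 1, 0, truth$center_diffusion_step_um)
      for (t in 2:n) {
        p <- ctr[t - 1] + steps[t - 1]
        if (p < lo) p <- 2 * lo - p
        if (p > hi) p <- 2 * hi - p
        ctr[t] <- min(max(p, lo), hi)
      }
    }

    # render all frames in one pass: expectations as an H x L x n array,
    # then a single Poisson + read-noise draw over the whole stack
    xpx <- seq_len(config$fov_length_px) - 0.5
    z1 <- outer(xpx, (ctr + ext / 2) / px, "-") / config$psf_sigma_px
    z2 <- outer(xpx, (ctr - ext / 2) / px, "-") / config$psf_sigma_px
    s_mat <- stats::pnorm(z2) - stats::pnorm(z1)  # Phi((x-c+w/2)/s) - Phi((x-c-w/2)/s)
    p_mat <- truth$plateau_amplitude * s_mat      # L x n along-channel signal
    wts <- transverse_weights(config)
    lam <- config$background_level +
      array(outer(wts, p_mat), dim = c(config$fov_height_px,
                                       config$fov_length_px, n))
    if (noise) {
      counts <- array(stats::rpois(length(lam), lam) +
                        stats::rnorm(length(lam), 0, config$read_noise_sd),
                      dim = dim(lam))
      counts <- pmax(counts, 0)
    } else counts <- lam
    frames <- lapply(seq_len(n), function(t) counts[, , t])
    structure(list(frames = frames,
                   pixel_size_um = px,
                   exposure_s = config$exposure_s,
                   truth = truth,
                   centers_um = ctr,
                   extensions_um = ext),
              class = "image_stack")
  })
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %dx%d px, %.3f um/px, %.0f ms exposure\n",
              length(x$frames), d[1], d[2], x$pixel_size_um,
              1000 * x$exposure_s))
  if (!is.null(x$truth))
    cat(sprintf("  truth: saturation %.3f, mean extension %.2f um\n",
                x$truth$saturation, x$truth$mean_extension_um))
  invisible(x)
}

#' Simulate a ground-truthed molecule population
#'
#' Draws per-molecule dye saturations ([sample_dye_loads()]), optionally
#' relaxes them toward equilibrium ([equilibrate_dye()]), adds
#' molecule-level extension scatter, and tabulates the rendering truth for
#' each molecule. Stacks themselves are rendered lazily (one at a time) by
#' [analyze_population()] or [run_simulate()] to keep memory flat.
#'
#' @param config a [sim_config()].
#' @param n_molecules population size.
#' @param mean_dye_per_bp sample-average dye:bp ratio (e.g. `1/5`).
#' @param heterogeneity staining spread parameter, see [sample_dye_loads()].
#' @param relaxation_rate,duration optional equilibration (per hour, hours).
#' @param seed master seed; per-molecule rendering seeds are derived from
#'   it deterministically.
#' @return object of class `sim_population`: list with `truth` (data frame
#'   with one row per molecule: `molecule_id`, `saturation`,
#'   `mean_extension_um`, `plateau_amplitude`, `seed`) and `config`.
#' @export
simulate_population <- function(config, n_molecules, mean_dye_per_bp,
                                heterogeneity = 1.5, relaxation_rate = 0,
                                duration = 0, seed = 1L) {
  validate_sim_config(config)
  if (n_molecules < 0L) stop("n_molecules must be >= 0", call. = FALSE)
  if (n_molecules == 0L) {
    truth <- data.frame(molecule_id = character(), saturation = numeric(),
                        mean_extension_um = numeric(),
                        plateau_amplitude = numeric(), seed = integer())
    return(structure(list(truth = truth, config = config),
                     class = "sim_population"))
  }
  theta <- sample_dye_loads(n_molecules, mean_dye_per_bp, heterogeneity,
                            seed = derive_seed(seed, 0),
                            dye_site_bp = config$dye_site_bp)
  if (relaxation_rate > 0 && duration > 0)
    theta <- pmin(1, pmax(0, equilibrate_dye(theta, relaxation_rate, duration)))
  offs <- with_seed(derive_seed(seed, 1),
                    stats::rnorm(n_molecules, 0, config$extension_scatter_um))
  rows <- lapply(seq_len(n_molecules), function(i) {
    tr <- molecule_truth(theta[i], config, extension_offset_um = offs[i])
    data.frame(molecule_id = sprintf("mol%05d", i),
               saturation = tr$saturation,
               mean_extension_um = tr$mean_extension_um,
               plateau_amplitude = tr$plateau_amplitude,
               seed = derive_seed(seed, i + 1L))
  })
  structure(list(truth = do.call(rbind, rows), config = config),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d molecules, condition '%s'\n",
              nrow(x$truth), x$config$condition_label))
  if (nrow(x$truth) > 0)
    cat(sprintf("  saturation: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$truth$saturation), min(x$truth$saturation),
                max(x$truth$saturation)))
  invisible(x)
}

# Rebuild the molecule_truth for row i of a sim_population truth table.
truth_from_row <- function(pop, i) {
  row <- pop$truth[i, ]
  tr <- list(saturation = row$saturation,
             mean_extension_um = row$mean_extension_um,
             plateau_amplitude = row$plateau_amplitude,
             extension_fluct_sd_um = pop$config$extension_fluct_sd_um,
             center_diffusion_step_um = pop$config$center_diffusion_step_um)
  class(tr) <- "molecule_truth"
  tr
}
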