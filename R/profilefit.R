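#' Extract a kymograph from an image stack
#'
#' Collapses each frame over the transverse axis (rows of the frame
#' matrices), giving one along-channel intensity profile per frame: the
#' standard kymograph (timetrace) representation used for single confined
#' molecules.
#'
#' @param stack an `image_stack` (from [render_stack()] or
#'   [read_stack_tiff()]).
#' @return object of class `kymograph`: list with `rows` (frames x pixels
#'   matrix), `pixel_size_um` and `frame_interval_s`.
#' @export
extract_kymograph <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) == 0L) stop("empty stack", call. = FALSE)
  rows <- t(vapply(stack$frames, colSums, numeric(ncol(stack$frames[[1]]))))
  if (length(stack$frames) == 1L) rows <- matrix(rows, nrow = 1L)
  structure(list(rows = rows,
                 pixel_size_um = stack$pixel_size_um,
                 frame_interval_s = stack$exposure_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d px, %.3f um/px\n",
              nrow(x$rows), ncol(x$rows), x$pixel_size_um))
  invisible(x)
}

# Deterministic, scale-free starting values for the profile fit:
# background from the outer 10% of pixels, amplitude from the peak,
# centre and width from the half-maximum crossings, sigma fixed at 2 px.
# Also returns the robust background-noise estimate used by the
# signal-present test. (Computed in compiled code; see src/.)
init_box_fit <- function(profile) {
  out <- .init_box_cpp(matrix(profile, nrow = 1))
  stats::setNames(drop(out), colnames(out))
}

fit_bounds <- function(L) {
  list(lower = c(0, 2, 0, -1e12, 0.1),
       upper = c(L, L, 1e12, 1e12, 10))
}

# Shared post-processing: C++ result matrix + pre-fit diagnostics ->
# tidy per-frame fit table in physical units. The signal-to-background
# threshold applies both to the initial amplitude (pre_ok) and to the
# fitted plateau: a fit that collapses the plateau into the noise while
# inflating the width is a runaway background fit, not a molecule.
fit_table <- function(res, pre_ok, noise, pixel_size_um, snr_min) {
  signal_ok <- pre_ok & res[, "plateau"] >= snr_min * pmax(noise, 1e-12)
  valid <- signal_ok & res[, "converged"] > 0 & res[, "at_bound"] == 0
  reason <- rep("ok", nrow(res))
  reason[!pre_ok] <- "no signal"
  reason[pre_ok & !signal_ok] <- "fitted amplitude below threshold"
  reason[signal_ok & res[, "at_bound"] > 0] <- "parameter at bound"
  reason[signal_ok & res[, "converged"] == 0] <- "no convergence"
  data.frame(
    frame = seq_len(nrow(res)),
    center_um = res[, "center_px"] * pixel_size_um,
    extension_um = res[, "width_px"] * pixel_size_um,
    plateau = res[, "plateau"],
    background = res[, "background"],
    blur_sigma_px = res[, "sigma_px"],
    integrated_intensity = res[, "plateau"] * res[, "width_px"] *
      pixel_size_um,
    residual_ss = res[, "rss"],
    valid = valid,
    reason = reason,
    row.names = NULL
  )
}

#' Fit one intensity profile with the box-erf edge model
#'
#' Least-squares estimation of centre, extension, plateau amplitude,
#' background and blur width under the [box_erf_profile()] model, by
#' Levenberg-Marquardt with an analytic Jacobian. Degenerate input never
#' raises from the optimizer: when the initial amplitude is below
#' `snr_min` times the robust background-noise estimate (median absolute
#' deviation of the outer pixels), when the optimizer fails, or when the
#' solution rests on a width/blur/amplitude bound, the frame is returned
#' with `valid = FALSE` and a `reason`. The bounds are
#' width in (2 px, window length), sigma in (0.1, 10) px, plateau > 0.
#'
#' @param profile numeric vector of intensities along the channel
#'   (>= 16 px, finite).
#' @param pixel_size_um pixel size used to convert to physical units.
#' @param init optional numeric vector `c(center, width, plateau,
#'   background, sigma)` in pixel units overriding the data-driven start.
#' @param snr_min signal-present threshold (default 3): minimum initial
#'   amplitude in units of the background noise. Molecules carrying too
#'   little dye to clear it constitute the "dark fraction".
#' @return one-row data frame (class `frame_fit`): `center_um`,
#'   `extension_um`, `plateau`, `background`, `blur_sigma_px`,
#'   `integrated_intensity` (= plateau x extension_um), `residual_ss`,
#'   `valid`, `reason`.
#' @export
fit_frame <- function(profile, pixel_size_um = 1, init = NULL, snr_min = 3) {
  if (length(profile) < 16L)
    stop("profile must have at least 16 pixels", call. = FALSE)
  if (any(!is.finite(profile)))
    stop("profile contains non-finite values", call. = FALSE)
  L <- length(profile)
  i0 <- init_box_fit(profile)
  pre_ok <- i0[["plateau"]] > 1e-6 &&
    i0[["plateau"]] >= snr_min * max(i0[["noise"]], 1e-12)
  p0 <- if (is.null(init)) i0[1:5] else as.numeric(init)
  b <- fit_bounds(L)
  res <- .fit_box_erf_cpp(matrix(profile, nrow = 1), matrix(p0, nrow = 1),
                          b$lower, b$upper)
  out <- fit_table(res, pre_ok, i0[["noise"]], pixel_size_um, snr_min)
  class(out) <- c("frame_fit", "data.frame")
  out
}

#' Fit every line of a kymograph
#'
#' Applies the [fit_frame()] estimator to each kymograph row with
#' per-row data-driven initialization; rows failing the signal-present
#' test are fitted anyway but flagged invalid.
#'
#' @param kymo a [extract_kymograph()] result.
#' @param snr_min see [fit_frame()].
#' @return data frame with one [fit_frame()] row per kymograph line.
#' @export
fit_kymograph <- function(kymo, snr_min = 3) {
  stopifnot(inherits(kymo, "kymograph"))
  L <- ncol(kymo$rows)
  if (L < 16L) stop("kymograph rows must have at least 16 pixels",
                    call. = FALSE)
  if (any(!is.finite(kymo$rows)))
    stop("kymograph contains non-finite values", call. = FALSE)
  ini <- .init_box_cpp(kymo$rows)
  pre_ok <- ini[, "plateau"] > 1e-6 &
    ini[, "plateau"] >= snr_min * pmax(ini[, "noise"], 1e-12)
  b <- fit_bounds(L)
  # frames with no detectable signal are not worth optimizing; they keep
  # their starting values and are flagged invalid
  res <- matrix(NA_real_, nrow(kymo$rows), 9,
                dimnames = list(NULL, c("center_px", "width_px", "plateau",
                                        "background", "sigma_px", "rss",
                                        "converged", "at_bound", "n_iter")))
  res[, 1:5] <- ini[, 1:5]
  res[, "converged"] <- 0
  res[, "at_bound"] <- 0
  if (any(pre_ok))
    res[pre_ok, ] <- .fit_box_erf_cpp(kymo$rows[pre_ok, , drop = FALSE],
                                      ini[pre_ok, 1:5, drop = FALSE],
                                      b$lower, b$upper)
  fit_table(res, pre_ok, ini[, "noise"], kymo$pixel_size_um, snr_min)
}

#' Align kymograph rows on the fitted molecule centre
#'
#' Circularly shifts each valid row by minus the (integer-pixel) offset of
#' its fitted centre from the median centre, so the molecule sits at the
#' same position in every line. Integer shifts keep photon counts exact;
#' invalid rows are carried through unshifted and listed in the
#' `unaligned_rows` attribute.
#'
#' @param kymo a `kymograph`.
#' @param fits the matching [fit_kymograph()] table (one row per line).
#' @return an aligned `kymograph` with attribute `unaligned_rows`.
#' @export
align_kymograph <- function(kymo, fits) {
  stopifnot(inherits(kymo, "kymograph"))
  if (nrow(fits) != nrow(kymo$rows))
    stop(sprintf("length mismatch: %d kymograph rows but %d fits",
                 nrow(kymo$rows), nrow(fits)), call. = FALSE)
  valid <- fits$valid
  if (!any(valid)) {
    warning("no valid frames; kymograph returned unaligned")
    out <- kymo
    attr(out, "unaligned_rows") <- seq_len(nrow(kymo$rows))
    return(out)
  }
  L <- ncol(kymo$rows)
  ref <- stats::median(fits$center_um[valid])
  shift <- -round((fits$center_um - ref) / kymo$pixel_size_um)
  rows <- kymo$rows
  for (t in which(valid & shift != 0)) {
    s <- ((shift[t] %% L) + L) %% L
    if (s != 0) rows[t, ] <- rows[t, c((L - s + 1):L, 1:(L - s))]
  }
  out <- kymo
  out$rows <- rows
  attr(out, "unaligned_rows") <- which(!valid)
  out
}

#' Time-average a molecule's per-frame fits
#'
#' Arithmetic mean and sample standard deviation of extension and
#' background-corrected integrated intensity over the *valid* frames
#' only. A molecule whose valid-frame fraction falls below
#' `min_valid_fraction` is flagged invalid (returned, never silently
#' dropped) -- this is how below-detection molecules exit the analysis.
#'
#' @param fits a [fit_kymograph()] table (>= 1 row).
#' @param min_valid_fraction minimum fraction of valid frames for the
#'   summary itself to count as valid (default 0.5).
#' @return one-row data frame: `mean_extension_um`, `extension_sd_um`,
#'   `mean_intensity`, `intensity_sd`, `n_valid_frames`, `n_total_frames`,
#'   `valid`.
#' @export
summarize_molecule <- function(fits, min_valid_fraction = 0.5) {
  if (nrow(fits) < 1L) stop("need at least one fit", call. = FALSE)
  v <- fits[fits$valid, , drop = FALSE]
  n_valid <- nrow(v)
  n_total <- nrow(fits)
  ok <- n_valid >= 1L && n_valid / n_total >= min_valid_fraction
  data.frame(
    mean_extension_um = if (n_valid) mean(v$extension_um) else NA_real_,
    extension_sd_um = if (n_valid > 1) stats::sd(v$extension_um) else
      if (n_valid == 1) 0 else NA_real_,
    mean_intensity = if (n_valid) mean(v$integrated_intensity) else NA_real_,
    intensity_sd = if (n_valid > 1) stats::sd(v$integrated_intensity) else
      if (n_valid == 1) 0 else NA_real_,
    n_valid_frames = n_valid,
    n_total_frames = n_total,
    valid = ok
  )
}
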