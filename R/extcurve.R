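#' Bin molecules by relative intensity
#'
#' Sorts molecules into contiguous half-open relative-intensity bins
#' (width 0.04 by default, anchored at zero) and computes the per-bin
#' mean extension, its standard error and the molecule count. Bins with
#' fewer than `min_per_bin` molecules are reported but flagged
#' unoccupied; with fewer than 2 molecules the SEM is undefined (NA).
#'
#' @param records data frame with columns `relative_intensity` and
#'   `mean_extension_um` (one row per molecule).
#' @param bin_width bin width on the relative-intensity axis (default
#'   0.04).
#' @param min_per_bin minimum count for a bin to be considered occupied
#'   (default 3; sparse bins destabilize downstream fits).
#' @param condition_label label carried into the result.
#' @return object of class `binned_curve`: data frame `bins` with
#'   `bin_lo`, `bin_hi`, `bin_center`, `mean_extension_um`,
#'   `extension_sem_um`, `n_molecules`, `occupied`; plus `bin_width`,
#'   `min_per_bin`, `condition_label`, `n_total`.
#' @export
bin_by_intensity <- function(records, bin_width = 0.04, min_per_bin = 3L,
                             condition_label = "") {
  if (is.null(nrow(records)) || nrow(records) == 0L)
    stop("records must be a non-empty data frame", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  x <- records$relative_intensity
  y <- records$mean_extension_um
  keep <- is.finite(x) & is.finite(y) & x >= 0
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L) stop("no finite records to bin", call. = FALSE)
  k <- floor(x / bin_width)
  kmax <- max(k)
  idx <- split(seq_along(x), factor(k, levels = 0:kmax))
  n <- vapply(idx, length, integer(1))
  mu <- vapply(idx, function(i) if (length(i)) mean(y[i]) else NA_real_,
               numeric(1))
  sem <- vapply(idx, function(i) if (length(i) > 1)
    stats::sd(y[i]) / sqrt(length(i)) else NA_real_, numeric(1))
  bins <- data.frame(
    bin_lo = bin_width * (0:kmax),
    bin_hi = bin_width * (1:(kmax + 1L)),
    bin_center = bin_width * (0:kmax + 0.5),
    mean_extension_um = mu,
    extension_sem_um = sem,
    n_molecules = as.integer(n),
    occupied = n >= min_per_bin,
    row.names = NULL
  )
  structure(list(bins = bins, bin_width = bin_width,
                 min_per_bin = as.integer(min_per_bin),
                 condition_label = condition_label,
                 n_total = length(x)),
            class = "binned_curve")
}

#' @export
print.binned_curve <- function(x, ...) {
  cat(sprintf("<binned_curve> '%s': %d molecules, %d occupied bins (width %.3g)\n",
              x$condition_label, x$n_total, sum(x$bins$occupied),
              x$bin_width))
  invisible(x)
}

#' Extrapolate the extension of native (dye-free) DNA
#'
#' Unweighted ordinary least squares of the per-bin mean extension on the
#' bin-centre relative intensity, over the first `n_bins` occupied bins
#' (counted upward from the lowest occupied bin; empty leading bins are
#' skipped with a message). The intercept is the extrapolated extension
#' of DNA with no dye bound; its OLS standard error is reported.
#'
#' @param curve a [bin_by_intensity()] result.
#' @param n_bins number of leading occupied bins in the fit (default 8).
#' @return object of class `extrapolation_result`: list with
#'   `native_extension_um`, `slope_um_per_unit`, `intercept_se`,
#'   `slope_se`, `n_bins_used`, `bin_centers`, `fit` (the `lm` object).
#' @export
extrapolate_native_extension <- function(curve, n_bins = 8L) {
  stopifnot(inherits(curve, "binned_curve"))
  occ <- which(curve$bins$occupied)
  if (length(occ) < n_bins)
    stop(sprintf("need %d occupied bins but only %d are occupied",
                 n_bins, length(occ)), call. = FALSE)
  use <- occ[seq_len(n_bins)]
  if (use[1] > 1L)
    message(sprintf("first %d bin(s) empty; fit starts at bin [%.3g, %.3g)",
                    use[1] - 1L, curve$bins$bin_lo[use[1]],
                    curve$bins$bin_hi[use[1]]))
  d <- data.frame(x = curve$bins$bin_center[use],
                  y = curve$bins$mean_extension_um[use])
  fit <- stats::lm(y ~ x, data = d)
  # summary.lm warns on an exactly collinear-free perfect fit; harmless here
  cf <- suppressWarnings(summary(fit)$coefficients)
  structure(list(native_extension_um = unname(cf[1, 1]),
                 slope_um_per_unit = unname(cf[2, 1]),
                 intercept_se = unname(cf[1, 2]),
                 slope_se = unname(cf[2, 2]),
                 n_bins_used = as.integer(n_bins),
                 bin_centers = d$x,
                 fit = fit),
            class = "extrapolation_result")
}

#' @export
print.extrapolation_result <- function(x, ...) {
  cat(sprintf("<extrapolation_result> native extension %.3f +/- %.3f um (slope %.2f um/unit, %d bins)\n",
              x$native_extension_um, x$intercept_se, x$slope_um_per_unit,
              x$n_bins_used))
  invisible(x)
}

#' Expected extension-versus-saturation model line
#'
#' The intercalation-only model line: starting from the native extension,
#' each bound dye adds `dye_extension_nm` of contour, and the confined
#' extension scales with contour length, so at relative intensity
#' \eqn{\theta} the expected extension is
#' `native * (1 + theta * dye_extension_nm / (dye_site_bp *
#' rise_per_bp_nm))` -- with the defaults, a 37.5% increase at
#' saturation. Identical in form to the simulator's extension law, so
#' deviations of data from this line isolate non-contour effects.
#'
#' @param native_extension_um extrapolated native extension (> 0).
#' @param dye_extension_nm contour added per dye (nm), default 0.51.
#' @param dye_site_bp basepairs per dye at saturation, default 4.
#' @param rise_per_bp_nm helical rise (nm/bp), default 0.34.
#' @param at relative intensities at which to tabulate the line.
#' @return object of class `model_line`: list with `points` (data frame
#'   `relative_intensity`, `expected_extension_um`), the parameters, and
#'   `predict(line, theta)` support via the stored closure `fun`.
#' @export
expected_extension_line <- function(native_extension_um,
                                    dye_extension_nm = 0.51,
                                    dye_site_bp = 4L,
                                    rise_per_bp_nm = 0.34,
                                    at = seq(0, 1, by = 0.02)) {
  if (!is.finite(native_extension_um) || native_extension_um <= 0)
    stop("native_extension_um must be > 0", call. = FALSE)
  rel <- dye_extension_nm / (dye_site_bp * rise_per_bp_nm)
  fun <- function(theta) native_extension_um * (1 + theta * rel)
  structure(list(points = data.frame(relative_intensity = at,
                                     expected_extension_um = fun(at)),
                 native_extension_um = native_extension_um,
                 dye_extension_nm = dye_extension_nm,
                 dye_site_bp = as.integer(dye_site_bp),
                 rise_per_bp_nm = rise_per_bp_nm,
                 fun = fun),
            class = "model_line")
}

#' @export
print.model_line <- function(x, ...) {
  cat(sprintf("<model_line> %.3f um x (1 + %.4g theta)\n",
              x$native_extension_um,
              x$dye_extension_nm / (x$dye_site_bp * x$rise_per_bp_nm)))
  invisible(x)
}

#' Per-bin extension ratio between two conditions
#'
#' Divides the binned mean extension of condition A by that of condition
#' B in every bin occupied in both curves, with first-order error
#' propagation: `se = ratio * sqrt((sem_a/mean_a)^2 + (sem_b/mean_b)^2)`.
#' A ratio that grows with dye load indicates that the dye's effect on
#' extension differs between the conditions beyond the shared contour
#' increase.
#'
#' @param curve_a,curve_b two [bin_by_intensity()] curves on identical
#'   bin grids (same width and origin).
#' @return data frame `bin_center`, `ratio`, `propagated_se`, plus an
#'   attribute `omitted_bins` listing bin centres occupied in only one
#'   curve.
#' @export
extension_ratio <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "binned_curve"), inherits(curve_b, "binned_curve"))
  if (abs(curve_a$bin_width - curve_b$bin_width) > 1e-12)
    stop("incompatible bin edges: widths differ", call. = FALSE)
  ka <- nrow(curve_a$bins); kb <- nrow(curve_b$bins)
  k <- min(ka, kb)
  a <- curve_a$bins[seq_len(k), ]
  b <- curve_b$bins[seq_len(k), ]
  both <- a$occupied & b$occupied
  only <- c(a$bin_center[a$occupied & !b$occupied],
            b$bin_center[b$occupied & !a$occupied],
            if (ka > k) curve_a$bins$bin_center[(k + 1):ka][
              curve_a$bins$occupied[(k + 1):ka]],
            if (kb > k) curve_b$bins$bin_center[(k + 1):kb][
              curve_b$bins$occupied[(k + 1):kb]])
  ratio <- a$mean_extension_um[both] / b$mean_extension_um[both]
  sem_a <- a$extension_sem_um[both]
  sem_b <- b$extension_sem_um[both]
  se <- ratio * sqrt((sem_a / a$mean_extension_um[both])^2 +
                       (sem_b / b$mean_extension_um[both])^2)
  out <- data.frame(bin_center = a$bin_center[both], ratio = ratio,
                    propagated_se = se, row.names = NULL)
  attr(out, "omitted_bins") <- sort(unique(only))
  out
}
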