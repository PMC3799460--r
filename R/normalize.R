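#' Estimate the population saturation-intensity limit
#'
#' Heterogeneously stained populations show a distinct upper limit in
#' per-molecule fluorescence intensity, interpreted as fully intercalated
#' DNA (one dye per 4 bp). The limit is estimated as an empirical quantile
#' (default the 97.5th percentile) of the pooled per-molecule intensities:
#' deterministic, robust to stray bright outliers, and configurable. Pool
#' equilibrated / high-dye samples when possible so the population
#' actually reaches saturation.
#'
#' @param intensities per-molecule mean integrated intensities (> 0);
#'   at least 20 molecules.
#' @param percentile quantile used as the upper-edge estimate (default
#'   0.975).
#' @return the saturation intensity (same units as input).
#' @export
estimate_saturation_intensity <- function(intensities, percentile = 0.975) {
  if (length(intensities) < 20L)
    stop(sprintf(paste0("need at least 20 molecules to identify the ",
                        "saturation limit (got %d); pool samples"),
                 length(intensities)), call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be positive and finite", call. = FALSE)
  if (percentile <= 0 || percentile > 1)
    stop("percentile must be in (0, 1]", call. = FALSE)
  unname(stats::quantile(intensities, percentile, type = 7))
}

#' Convert raw intensities to relative (saturation-normalized) intensities
#'
#' Divides each molecule's time-averaged intensity by the saturation
#' limit. Under linear emission, the result is the molecule's dye
#' saturation (fraction of the 1-per-4-bp maximum). Values above 1
#' (molecules brighter than the estimated limit) are retained and counted
#' in `n_clipped`, never silently clipped, so estimator bias stays
#' visible.
#'
#' @param summaries a data frame of molecule summaries with columns
#'   `mean_intensity` and (optionally) `molecule_id`; typically valid rows
#'   of [analyze_population()] output.
#' @param saturation_intensity the limit from
#'   [estimate_saturation_intensity()] (> 0). Pass a per-condition
#'   override where the constant-quantum-yield assumption is rejected
#'   (e.g. high-salt conditions where the observed maximum is halved).
#' @param method_label free-text provenance label.
#' @return object of class `normalization_result`: list with
#'   `saturation_intensity`, `method_label`, `relative_intensities`
#'   (named vector), `n_clipped`.
#' @export
relative_intensity <- function(summaries, saturation_intensity,
                               method_label = "empirical quantile") {
  if (!is.finite(saturation_intensity) || saturation_intensity <= 0)
    stop("saturation_intensity must be > 0", call. = FALSE)
  vals <- summaries$mean_intensity / saturation_intensity
  names(vals) <- if (!is.null(summaries$molecule_id)) summaries$molecule_id
    else as.character(seq_along(vals))
  structure(list(saturation_intensity = saturation_intensity,
                 method_label = method_label,
                 relative_intensities = vals,
                 n_clipped = sum(vals > 1, na.rm = TRUE)),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("<normalization_result> limit %.4g (%s), %d molecules, %d above 1\n",
              x$saturation_intensity, x$method_label,
              length(x$relative_intensities), x$n_clipped))
  invisible(x)
}

#' Fraction of molecules below the detection limit
#'
#' At low dye loads part of the population carries too little dye to be
#' seen above the noise floor -- the "dark fraction". Because detection
#' selects on brightness, detected molecules over-represent the bright
#' tail and their mean intensity exceeds the true population mean.
#'
#' @param truth_count number of molecules present (e.g. simulated).
#' @param detected_count number of validly detected molecule summaries.
#' @return `1 - detected_count / truth_count`.
#' @export
dark_fraction <- function(truth_count, detected_count) {
  if (truth_count < 0 || detected_count < 0)
    stop("counts must be >= 0", call. = FALSE)
  if (detected_count > truth_count)
    stop(sprintf("bookkeeping error: %d detected > %d simulated",
                 detected_count, truth_count), call. = FALSE)
  if (truth_count == 0L) return(0)
  1 - detected_count / truth_count
}

#' Fixed-width intensity histogram
#'
#' Histograms relative intensities in contiguous half-open bins
#' `[k*bin_width, (k+1)*bin_width)` anchored at zero, for
#' population-distribution plots (intensity fractions per sample).
#'
#' @param values non-negative intensity values.
#' @param bin_width bin width (> 0), default 0.04.
#' @return object of class `intensity_histogram`: list with `bin_edges`,
#'   `counts` (summing to `n_total`), `n_total`.
#' @export
intensity_histogram <- function(values, bin_width = 0.04) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    return(structure(list(bin_edges = numeric(), counts = integer(),
                          n_total = 0L), class = "intensity_histogram"))
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  k <- floor(values / bin_width)  # half-open: x = edge goes to upper bin
  kmax <- max(k)
  counts <- tabulate(k + 1L, nbins = kmax + 1L)
  structure(list(bin_edges = bin_width * (0:(kmax + 1L)),
                 counts = counts,
                 n_total = length(values)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d values in %d bins\n",
              x$n_total, length(x$counts)))
  invisible(x)
}
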