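#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' Photon counts are stored as 16-bit integers (values clipped to
#' 0..65535); [read_stack_tiff()] restores them.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(stack$frames, function(f) pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file path.
#' @param pixel_size_um,exposure_s acquisition metadata (not stored in the
#'   TIFF).
#' @return an `image_stack` (with `truth = NULL`).
#' @export
read_stack_tiff <- function(path, pixel_size_um, exposure_s = 0.1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    round(p * 65535)
  })
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 exposure_s = exposure_s, truth = NULL),
            class = "image_stack")
}

#' Analyze a simulated population end to end, in memory
#'
#' For each molecule of a [simulate_population()] cohort: render the
#' image stack with the molecule's derived seed, extract the kymograph,
#' fit every line with the box-erf model, align, and time-average the
#' fits. Stacks are discarded after use so memory stays flat at
#' population scale.
#'
#' @param pop a `sim_population`.
#' @param min_valid_fraction see [summarize_molecule()].
#' @param snr_min see [fit_frame()].
#' @param align also run the kymograph alignment step (the summaries do
#'   not depend on it; default TRUE for pipeline fidelity).
#' @param progress print a progress line every 500 molecules.
#' @return data frame with one row per simulated molecule: `molecule_id`,
#'   truth columns (`saturation`, `true_extension_um`), and the summary
#'   columns of [summarize_molecule()].
#' @export
analyze_population <- function(pop, min_valid_fraction = 0.5, snr_min = 3,
                               align = TRUE, progress = FALSE) {
  stopifnot(inherits(pop, "sim_population"))
  n <- nrow(pop$truth)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- truth_from_row(pop, i)
    stack <- render_stack(tr, pop$config, seed = pop$truth$seed[i])
    kymo <- extract_kymograph(stack)
    fits <- fit_kymograph(kymo, snr_min = snr_min)
    if (align && any(fits$valid))
      invisible(align_kymograph(kymo, fits))
    s <- summarize_molecule(fits, min_valid_fraction = min_valid_fraction)
    s$molecule_id <- pop$truth$molecule_id[i]
    s$saturation <- pop$truth$saturation[i]
    s$true_extension_um <- pop$truth$mean_extension_um[i]
    out[[i]] <- s
    if (progress && i %% 500L == 0L)
      message(sprintf("  analyzed %d / %d molecules", i, n))
  }
  res <- do.call(rbind, out)
  front <- c("molecule_id", "saturation", "true_extension_um")
  res[, c(front, setdiff(names(res), front))]
}

#' Normalize, bin and extrapolate a set of molecule summaries
#'
#' The population-level tail of the pipeline: estimate (or accept) the
#' saturation intensity, convert to relative intensities, bin extension
#' by relative intensity, and extrapolate the native extension from the
#' first `n_bins` occupied bins.
#'
#' @param summaries data frame with `mean_intensity`,
#'   `mean_extension_um`, `valid` columns (e.g. [analyze_population()]
#'   output); only valid rows are used.
#' @param saturation_intensity optional fixed limit; estimated from the
#'   data with `percentile` when NULL.
#' @param percentile see [estimate_saturation_intensity()].
#' @param bin_width,min_per_bin see [bin_by_intensity()].
#' @param n_bins see [extrapolate_native_extension()].
#' @param condition_label label for the curve.
#' @return list with `normalization` ([relative_intensity()] result),
#'   `records` (per-molecule data frame), `curve` (`binned_curve`) and
#'   `extrapolation` (`extrapolation_result`).
#' @export
analyze_extension_curve <- function(summaries, saturation_intensity = NULL,
                                    percentile = 0.975, bin_width = 0.04,
                                    min_per_bin = 3L, n_bins = 8L,
                                    condition_label = "") {
  det <- summaries[summaries$valid, , drop = FALSE]
  if (nrow(det) == 0L) stop("no valid molecules to analyze", call. = FALSE)
  if (is.null(saturation_intensity))
    saturation_intensity <-
      estimate_saturation_intensity(det$mean_intensity, percentile)
  norm <- relative_intensity(det, saturation_intensity)
  records <- data.frame(molecule_id = names(norm$relative_intensities),
                        relative_intensity =
                          unname(norm$relative_intensities),
                        mean_extension_um = det$mean_extension_um)
  curve <- bin_by_intensity(records, bin_width = bin_width,
                            min_per_bin = min_per_bin,
                            condition_label = condition_label)
  extrap <- extrapolate_native_extension(curve, n_bins = n_bins)
  list(normalization = norm, records = records, curve = curve,
       extrapolation = extrap)
}

#' Load a run configuration from YAML or JSON
#'
#' The scenario file holds a `sim` block (passed to [sim_config()]) plus
#' population (`n_molecules`, `mean_dye_per_bp`, `heterogeneity`,
#' `relaxation_rate`, `duration`), analysis (`snr_min`,
#' `min_valid_fraction`, `percentile`, `bin_width`, `min_per_bin`,
#' `n_bins`) and `seed` settings. Missing entries fall back to package
#' defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return a named list (class `run_config`) with a built `sim_config`
#'   under `$config`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- do.call(sim_config, as.list(raw$sim %||% list()))
  defaults <- list(n_molecules = 100L, mean_dye_per_bp = 0.1,
                   heterogeneity = 1.5, relaxation_rate = 0, duration = 0,
                   snr_min = 3, min_valid_fraction = 0.5, percentile = 0.975,
                   bin_width = 0.04, min_per_bin = 3L, n_bins = 8L, seed = 1L)
  rc <- utils::modifyList(defaults, raw[setdiff(names(raw), "sim")])
  rc$config <- cfg
  class(rc) <- "run_config"
  rc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a population to disk
#'
#' Renders every molecule of the configured population and writes one
#' multi-page TIFF per molecule, a ground-truth CSV, a manifest listing
#' every artifact, and an echo of the effective configuration -- all
#' deterministic for a fixed seed.
#'
#' @param rc a [load_run_config()] result (or an equivalent list).
#' @param out_dir output directory (created; must be writable).
#' @return invisibly, a list with `manifest` (data frame) and paths.
#' @export
run_simulate <- function(rc, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop(sprintf("output path '%s' is not writable", out_dir), call. = FALSE)
  pop <- simulate_population(rc$config, rc$n_molecules, rc$mean_dye_per_bp,
                             heterogeneity = rc$heterogeneity,
                             relaxation_rate = rc$relaxation_rate,
                             duration = rc$duration, seed = rc$seed)
  echo_config(rc, out_dir)
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(format(pop$truth, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   truth_path, row.names = FALSE, quote = FALSE)
  files <- character(nrow(pop$truth))
  for (i in seq_len(nrow(pop$truth))) {
    tr <- truth_from_row(pop, i)
    stack <- render_stack(tr, pop$config, seed = pop$truth$seed[i])
    files[i] <- file.path(out_dir,
                          paste0(pop$truth$molecule_id[i], ".tif"))
    write_stack_tiff(stack, files[i])
  }
  manifest <- data.frame(molecule_id = pop$truth$molecule_id,
                         file = basename(files))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  if (nrow(manifest) == 0L)
    warning("n_molecules = 0: empty manifest written")
  invisible(list(manifest = manifest, truth_path = truth_path,
                 out_dir = out_dir))
}

echo_config <- function(rc, out_dir) {
  flat <- rc[setdiff(names(rc), "config")]
  flat$sim <- unclass(rc$config)
  flat$package_version <- as.character(utils::packageVersion("nanostain"))
  yaml::write_yaml(flat, file.path(out_dir, "effective_config.yaml"))
}

#' Analyze a directory of molecule TIFF stacks
#'
#' File-based counterpart of [analyze_population()] +
#' [analyze_extension_curve()]: reads every stack named in
#' `manifest.csv` (or every `*.tif` when no manifest exists), runs
#' extract, fit, align and summarize per molecule, then normalizes,
#' bins and extrapolates. Unreadable stacks are skipped with a logged
#' reason; the run fails only if *no* molecule survives. Writes
#' `summaries.csv`, `records.csv`, `curve.csv`, `histogram.csv`,
#' `extrapolation.json`, `skip_log.csv` and the effective config into
#' `out_dir`.
#'
#' @param rc a [load_run_config()] result.
#' @param stacks_dir directory produced by [run_simulate()] (or holding
#'   equivalent TIFFs).
#' @param out_dir output directory.
#' @return invisibly, a list with `summaries`, `skip_log`, and the
#'   [analyze_extension_curve()] components.
#' @export
run_analyze <- function(rc, stacks_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop(sprintf("output path '%s' is not writable", out_dir), call. = FALSE)
  man_path <- file.path(stacks_dir, "manifest.csv")
  files <- if (file.exists(man_path)) {
    man <- utils::read.csv(man_path)
    stats::setNames(file.path(stacks_dir, man$file), man$molecule_id)
  } else {
    f <- list.files(stacks_dir, pattern = "\\.tiff?$", full.names = TRUE)
    stats::setNames(f, sub("\\.tiff?$", "", basename(f)))
  }
  summaries <- list()
  skips <- list()
  for (id in names(files)) {
    s <- tryCatch({
      stack <- read_stack_tiff(files[[id]], rc$config$pixel_size_um,
                               rc$config$exposure_s)
      kymo <- extract_kymograph(stack)
      fits <- fit_kymograph(kymo, snr_min = rc$snr_min)
      if (any(fits$valid)) invisible(align_kymograph(kymo, fits))
      summarize_molecule(fits, min_valid_fraction = rc$min_valid_fraction)
    }, error = function(e) e)
    if (inherits(s, "error")) {
      skips[[id]] <- data.frame(molecule_id = id,
                                reason = conditionMessage(s))
      next
    }
    s$molecule_id <- id
    summaries[[id]] <- s
  }
  skip_log <- if (length(skips)) do.call(rbind, skips) else
    data.frame(molecule_id = character(), reason = character())
  if (length(summaries) == 0L)
    stop("all molecules were skipped; see skip log", call. = FALSE)
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  echo_config(rc, out_dir)
  utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(skip_log, file.path(out_dir, "skip_log.csv"),
                   row.names = FALSE)
  res <- analyze_extension_curve(summaries,
                                 percentile = rc$percentile,
                                 bin_width = rc$bin_width,
                                 min_per_bin = rc$min_per_bin,
                                 n_bins = rc$n_bins,
                                 condition_label =
                                   rc$config$condition_label)
  utils::write.csv(res$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$curve$bins, file.path(out_dir, "curve.csv"),
                   row.names = FALSE, quote = FALSE)
  hist <- intensity_histogram(res$records$relative_intensity,
                              bin_width = rc$bin_width)
  utils::write.csv(data.frame(bin_lo = utils::head(hist$bin_edges, -1),
                              bin_hi = hist$bin_edges[-1],
                              count = hist$counts),
                   file.path(out_dir, "histogram.csv"), row.names = FALSE,
                   quote = FALSE)
  ex <- res$extrapolation
  jsonlite::write_json(list(native_extension_um = ex$native_extension_um,
                            slope_um_per_unit = ex$slope_um_per_unit,
                            intercept_se = ex$intercept_se,
                            slope_se = ex$slope_se,
                            n_bins_used = ex$n_bins_used,
                            saturation_intensity =
                              res$normalization$saturation_intensity,
                            n_molecules = nrow(summaries),
                            n_skipped = nrow(skip_log)),
                       file.path(out_dir, "extrapolation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(list(summaries = summaries, skip_log = skip_log), res))
}
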