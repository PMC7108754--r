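#' Write a B-M series dataset to disk
#'
#' One multi-page TIFF per trial (pages = frames, 32-bit samples)
#' plus a JSON sidecar holding the acquisition protocol, modality,
#' frame rate, exposure, array dimensions, the intensity scale
#' factor, and the ground truth (when the series is synthetic). TIFF
#' samples live in [0, 1], so intensities are divided by the recorded
#' power-of-two `scale` on write and multiplied back on load; a
#' write-load cycle is exact to one 32-bit quantum (`scale * 2^-32`).
#'
#' @param series a `bm_series`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @seealso [load_dataset()]
#' @export
write_dataset <- function(series, dir) {
  stopifnot(inherits(series, "bm_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(series$data[[1]])
  # power-of-two scale: division/multiplication only touch the
  # exponent, so a write-load cycle is exactly idempotent at float32
  mx <- max(vapply(series$data, max, numeric(1)))
  scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  files <- character(length(series$data))
  for (i in seq_along(series$data)) {
    files[i] <- sprintf("%s_trial_%03d.tif", series$modality, i)
    pages <- lapply(seq_len(d[3]),
                    function(k) series$data[[i]][, , k] / scale)
    tiff::writeTIFF(pages, file.path(dir, files[i]), bits.per.sample = 32)
  }
  gt <- series$ground_truth
  gt_json <- NULL
  if (!is.null(gt) && inherits(gt, "ground_truth")) {
    gt_json <- list(
      activation_idx = which(gt$activation),
      vessel_idx = if (!is.null(gt$vessel_mask)) which(gt$vessel_mask),
      tail_idx = if (!is.null(gt$tail_mask)) which(gt$tail_mask),
      template = unclass(gt$template),
      hemo_onset_s = gt$hemo_onset_s,
      amp_jitter = gt$amp_jitter,
      seed = gt$seed, stim = gt$stim)
  }
  sidecar <- list(format = "insfoct-dataset",
                  modality = series$modality, fps = series$fps,
                  exposure = series$exposure,
                  n_trials = length(series$data),
                  dims = d, scale = scale, files = files,
                  protocol = unclass(series$protocol),
                  velocity_mm_s = series$velocity_mm_s,
                  ground_truth = gt_json)
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a B-M series dataset from disk
#'
#' Reads the layout written by [write_dataset()] and validates the
#' arrays against the sidecar. Failures raise distinct condition
#' classes: `insfoct_missing_sidecar`, `insfoct_shape_mismatch`,
#' `insfoct_nan_pixels`.
#'
#' @param dir dataset directory.
#' @return A `bm_series`.
#' @export
load_dataset <- function(dir) {
  sc_path <- file.path(dir, "dataset.json")
  if (!file.exists(sc_path))
    stop(errorCondition(paste0("no dataset.json sidecar in ", dir),
                        class = c("insfoct_missing_sidecar", "error")))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  pr <- sc$protocol
  protocol <- ins_protocol(pr$prestim_s, pr$stim_s, pr$poststim_s,
                           pr$n_trials, pr$oct_fps, pr$oisi_fps,
                           pr$pulse_width_us, pr$pulse_rate_hz,
                           pr$radiant_exposures, pr$z_pitch_um,
                           pr$x_pitch_um, pr$n_z, pr$n_x)
  d <- as.integer(sc$dims)
  trials <- vector("list", sc$n_trials)
  for (i in seq_len(sc$n_trials)) {
    pages <- tiff::readTIFF(file.path(dir, sc$files[i]), all = TRUE)
    if (length(pages) != d[3] || !all(dim(pages[[1]]) == d[1:2]))
      stop(errorCondition(
        sprintf("stack %s has shape %d x %d x %d but sidecar declares %s",
                sc$files[i], dim(pages[[1]])[1], dim(pages[[1]])[2],
                length(pages), paste(d, collapse = " x ")),
        class = c("insfoct_shape_mismatch", "error")))
    a <- array(unlist(pages), dim = c(d[1], d[2], d[3])) * sc$scale
    if (any(!is.finite(a)))
      stop(errorCondition(sprintf("non-finite pixels in %s", sc$files[i]),
                          class = c("insfoct_nan_pixels", "error")))
    trials[[i]] <- a
  }
  gt <- NULL
  if (!is.null(sc$ground_truth)) {
    g <- sc$ground_truth
    asmask <- function(idx) {
      m <- matrix(FALSE, d[1], d[2])
      if (length(idx)) m[idx] <- TRUE
      m
    }
    tpl <- g$template
    gt <- structure(list(
      activation = asmask(g$activation_idx),
      vessel_mask = if (!is.null(g$vessel_idx)) asmask(g$vessel_idx),
      tail_mask = if (!is.null(g$tail_idx)) asmask(g$tail_idx),
      template = response_template(
        onset_delay_s = tpl$onset_delay_s,
        peak_delay_s = tpl$peak_delay_s,
        peak_amplitude = tpl$peak_amplitude,
        decay_tau_s = tpl$decay_tau_s, sign = tpl$sign,
        amplitude_vs_exposure_slope = tpl$amplitude_vs_exposure_slope),
      hemo_onset_s = g$hemo_onset_s,
      amp_jitter = g$amp_jitter, seed = g$seed, stim = g$stim),
      class = "ground_truth")
  }
  structure(list(data = trials, protocol = protocol, fps = sc$fps,
                 exposure = sc$exposure, modality = sc$modality,
                 trial_index = seq_len(sc$n_trials),
                 velocity_mm_s = sc$velocity_mm_s,
                 ground_truth = gt),
            class = "bm_series")
}

#' Write spike timestamps as CSV
#'
#' Two columns, `trial` and `timestamp_s` (INS-onset-locked).
#'
#' @param spikes a `spike_data` or list of per-trial timestamp
#'   vectors.
#' @param file output CSV path.
#' @export
write_spikes <- function(spikes, file) {
  trials <- if (inherits(spikes, "spike_data")) spikes$trials else spikes
  df <- data.frame(
    trial = rep(seq_along(trials), lengths(trials)),
    timestamp_s = unlist(trials, use.names = FALSE))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read spike timestamps from CSV
#'
#' @param file CSV written by [write_spikes()].
#' @param n_trials total trial count (trailing trials may be empty).
#' @return List of per-trial timestamp vectors.
#' @export
load_spikes <- function(file, n_trials = NULL) {
  df <- utils::read.csv(file)
  if (is.null(n_trials)) n_trials <- max(df$trial, 1)
  lapply(seq_len(n_trials), function(i) sort(df$timestamp_s[df$trial == i]))
}

# flatten a time_course into the standard results table layout
tc_to_table <- function(tc, condition = "", depth_bin = NA) {
  data.frame(time_s = tc$time_s, value = tc$value,
             condition = condition, depth_bin = depth_bin)
}

#' Write analysis results to disk
#'
#' Tables (time courses, dose tables, latency tables) as CSV with
#' headers; maps as 32-bit float TIFF (scaled into [0, 1], the scale
#' recorded in the report); a JSON run report carrying every
#' threshold and parameter used.
#'
#' @param tables named list of data frames.
#' @param maps named list of numeric matrices (may be `NULL`).
#' @param path output directory.
#' @param report named list for the JSON run report.
#' @return Invisibly, the list of files written.
#' @export
write_results <- function(tables, maps = NULL, path, report = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  map_scales <- list()
  for (nm in names(maps)) {
    m <- maps[[nm]]
    m[!is.finite(m)] <- 0
    sc <- max(1e-12, max(abs(m)))
    f <- file.path(path, paste0(nm, ".tif"))
    tiff::writeTIFF(pmin(pmax(m / sc, 0), 1), f, bits.per.sample = 32)
    map_scales[[nm]] <- sc
    files <- c(files, f)
  }
  report$map_scales <- map_scales
  f <- file.path(path, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  files <- c(files, f)
  invisible(files)
}
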