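#' Analysis configuration
#'
#' Collects every threshold and parameter of the fOCT analysis so a
#' run can be reproduced from its report. Defaults are the standard
#' settings: 3-sigma / 5-frame adaptive significance, 6-sigma
#' intensity mask over the noise floor, a 3 x 3 decorrelation window
#' with Otsu vessel binarization and tail extension, six 100-um depth
#' bins, and the 3-sigma onset criterion.
#'
#' @param k_sigma significance threshold multiplier.
#' @param run_length consecutive frames required for significance.
#' @param intensity_factor noise-floor multiplier of the intensity
#'   mask.
#' @param decorr_window decorrelation window `(wz, wx)`.
#' @param vessel_threshold fixed decorrelation binarization threshold,
#'   or `NULL` for Otsu's method on the temporal-mean angiogram.
#' @param tail_extend extend vessel masks down each A-line.
#' @param noise_rows_frac fraction of the deepest rows used as the
#'   noise region.
#' @param pooling `"pixel"` or `"frame"`, see [aggregate_foct()].
#' @param depth_bin_um,depth_bins depth-resolved binning.
#' @param onset_k onset-latency threshold multiplier.
#' @param oisi_roi_px OISI ROI edge length (pixels).
#' @param psth_bin_ms PSTH bin width for spike-onset analysis.
#' @return An object of class `ins_config`.
#' @export
ins_config <- function(k_sigma = 3, run_length = 5, intensity_factor = 6,
                       decorr_window = c(3, 3), vessel_threshold = NULL,
                       tail_extend = TRUE, noise_rows_frac = 0.1,
                       pooling = c("pixel", "frame"),
                       depth_bin_um = 100, depth_bins = 6,
                       onset_k = 3, oisi_roi_px = 20, psth_bin_ms = 1) {
  structure(list(k_sigma = k_sigma, run_length = run_length,
                 intensity_factor = intensity_factor,
                 decorr_window = decorr_window,
                 vessel_threshold = vessel_threshold,
                 tail_extend = tail_extend,
                 noise_rows_frac = noise_rows_frac,
                 pooling = match.arg(pooling),
                 depth_bin_um = depth_bin_um, depth_bins = depth_bins,
                 onset_k = onset_k, oisi_roi_px = oisi_roi_px,
                 psth_bin_ms = psth_bin_ms),
            class = "ins_config")
}

#' Run the fOCT analysis chain on a synthetic B-M dataset
#'
#' Streams trials through the full chain -- simulation, prestimulus
#' baseline, adaptive significance, decorrelation angiography with
#' avascular masking, noise-floor intensity masking, fractional
#' change, sign-normalized pooling -- and averages the per-trial
#' pooled courses, holding only one trial's stack in memory at a
#' time. With `stim = FALSE` a blank condition is analyzed instead.
#'
#' @param protocol an [ins_protocol()].
#' @param scene an [ins_scene()].
#' @param exposure radiant exposure (J/cm^2).
#' @param seed integer seed (drives the generator).
#' @param config an [ins_config()].
#' @param fps OCT frame rate; defaults to `protocol$oct_fps`.
#' @param stim simulate stimulation (`TRUE`) or blank (`FALSE`).
#' @param depth also compute depth-resolved courses.
#' @param response_window_s window for the significant-pixel count.
#' @return An object of class `foct_run`: the averaged [time_course()]
#'   `tc`, per-trial pooled-pixel counts `n_pixels`, per-trial
#'   significant-pixel counts `sig_counts` (response window, masked),
#'   optional `depth` course list, the masks of the last trial, and
#'   the configuration.
#' @export
run_foct_pipeline <- function(protocol, scene, exposure = 1.0, seed,
                              config = ins_config(),
                              fps = protocol$oct_fps, stim = TRUE,
                              depth = FALSE,
                              response_window_s = c(0, 1)) {
  validate_protocol(protocol)
  stopifnot(inherits(scene, "ins_scene"), inherits(config, "ins_config"))
  set.seed(as.integer(seed))
  jit <- pmax(0.1, 1 + scene$trial_cv * stats::rnorm(protocol$n_trials))
  nt <- as.integer(round(trial_duration(protocol) * fps))
  npre <- as.integer(round(protocol$prestim_s * fps))
  tt <- (seq_len(nt) - 1) / fps - protocol$prestim_s
  win <- which(tt >= response_window_s[1] & tt < response_window_s[2])
  nz <- protocol$n_z; nx <- protocol$n_x; npx <- nz * nx

  V <- matrix(NA_real_, nt, protocol$n_trials)
  Np <- matrix(0, nt, protocol$n_trials)
  sig_counts <- numeric(protocol$n_trials)
  if (depth) {
    z_um <- (seq_len(nz) - 1) * protocol$z_pitch_um
    Vd <- array(NA_real_, c(nt, protocol$n_trials, config$depth_bins))
  }
  masks <- NULL
  for (tr in seq_len(protocol$n_trials)) {
    arr <- sim_bm_trial(protocol, scene, exposure, fps,
                        amp_jitter = if (stim) jit[tr] else 0, stim = stim)
    bl <- compute_baseline(arr, n_prestim = npre)
    sig <- detect_significant(arr, bl, config$k_sigma, config$run_length)
    cov <- significance_coverage(sig)
    sig <- NULL
    ang <- angiogram_series(arr, window = config$decorr_window)
    vm <- build_vascular_mask(ang, threshold = config$vessel_threshold,
                              tail_extend = config$tail_extend)
    ang <- NULL
    nf <- estimate_noise_floor(arr[, , seq_len(npre), drop = FALSE],
                               rows_frac = config$noise_rows_frac,
                               prestim_only = FALSE)
    im <- intensity_mask(bl, nf$mean, nf$sd, config$intensity_factor)
    keep <- vm$avascular & im
    drr <- fractional_change(arr, bl)
    arr <- NULL
    p <- pool_trial(drr, cov, keep, config$pooling)
    V[, tr] <- p$value
    Np[, tr] <- p$n
    covm <- cov; dim(covm) <- c(npx, nt)
    sig_counts[tr] <- sum(rowSums(covm[, win, drop = FALSE] != 0L) > 0 &
                          as.vector(keep))
    if (depth) {
      for (b in seq_len(config$depth_bins)) {
        inbin <- z_um >= (b - 1) * config$depth_bin_um &
                 z_um < b * config$depth_bin_um
        pb <- pool_trial(drr, cov, keep & matrix(inbin, nz, nx),
                         config$pooling)
        Vd[, tr, b] <- pb$value
      }
    }
    masks <- list(avascular = vm$avascular, intensity = im,
                  vessel_threshold = vm$threshold,
                  noise_floor = nf, baseline = bl)
    drr <- NULL; cov <- NULL; covm <- NULL
  }
  avg <- function(M) {
    if (is.null(dim(M))) return(M)   # single trial
    v <- rowMeans(M, na.rm = TRUE)
    v[rowSums(!is.na(M)) == 0] <- NA_real_
    v
  }
  tc <- time_course(tt, avg(V), n_pixels = rowMeans(Np),
                    condition = list(exposure = exposure,
                                     stim = stim, fps = fps))
  attr(tc, "pooling") <- config$pooling
  depth_tcs <- NULL
  if (depth)
    depth_tcs <- lapply(seq_len(config$depth_bins), function(b)
      time_course(tt, avg(Vd[, , b, drop = TRUE]),
                  condition = list(exposure = exposure, depth_bin = b)))
  structure(list(tc = tc, depth = depth_tcs,
                 n_pixels = Np[1, ], sig_counts = sig_counts,
                 masks = masks, config = config, protocol = protocol,
                 exposure = exposure, fps = fps, seed = as.integer(seed),
                 stim = stim),
            class = "foct_run")
}

#' @export
print.foct_run <- function(x, ...) {
  cat(sprintf("fOCT pipeline run: exposure %g J/cm2, %d trials at %g fps%s\n",
              x$exposure, x$protocol$n_trials, x$fps,
              if (!x$stim) " (blank)" else ""))
  cat(sprintf("  pooled pixels/trial: %s; significant pixels (response window): %.1f\n",
              paste(range(x$n_pixels), collapse = "-"),
              mean(x$sig_counts)))
  ok <- is.finite(x$tc$value)
  if (any(ok))
    cat(sprintf("  course peak |dR/R| = %.4g at t = %.3f s\n",
                max(abs(x$tc$value[ok])),
                x$tc$time_s[ok][which.max(abs(x$tc$value[ok]))]))
  invisible(x)
}

#' Streamed blood-flow velocity-index time course
#'
#' Simulates and analyzes the hemodynamic velocity index trial by
#' trial (one stack in memory at a time): each trial's adjacent-frame
#' decorrelation maps are averaged over the ROI (default: the scene's
#' programmed vessel pixels) and the per-pair courses are averaged
#' across trials. Equivalent to [simulate_bm_series()] followed by
#' [velocity_index()] with the same seed.
#'
#' @inheritParams run_foct_pipeline
#' @param roi region of interest (logical mask, index matrix or
#'   linear indices); `NULL` uses the scene's vessel pixels.
#' @param window decorrelation window.
#' @return A [time_course()] of decorrelation values.
#' @export
run_velocity_pipeline <- function(protocol, scene, exposure = 1.0, seed,
                                  roi = NULL, window = c(3, 3),
                                  fps = protocol$oct_fps) {
  validate_protocol(protocol)
  stopifnot(inherits(scene, "ins_scene"))
  if (is.null(roi)) {
    roi <- scene_moving_pixels(scene)$vessel_mask
    if (!any(roi)) stop("scene has no vessels; supply an roi")
  }
  idx <- roi_indices(roi, protocol$n_z, protocol$n_x)
  set.seed(as.integer(seed))
  jit <- pmax(0.1, 1 + scene$trial_cv * stats::rnorm(protocol$n_trials))
  nt <- as.integer(round(trial_duration(protocol) * fps))
  npx <- protocol$n_z * protocol$n_x
  acc <- numeric(nt - 1L)
  for (tr in seq_len(protocol$n_trials)) {
    arr <- sim_bm_trial(protocol, scene, exposure, fps, jit[tr])
    ang <- angiogram_series(arr, window = window)
    arr <- NULL
    M <- ang$maps
    dim(M) <- c(npx, nt - 1L)
    acc <- acc + colMeans(M[idx, , drop = FALSE])
    ang <- NULL; M <- NULL
  }
  tt <- (seq_len(nt) - 1) / fps - protocol$prestim_s
  time_course(time_s = tt[-1], value = acc / protocol$n_trials,
              n_pixels = length(idx),
              condition = list(signal = "velocity_index",
                               exposure = exposure))
}

#' End-to-end pipeline run with on-disk outputs
#'
#' Orchestrates a complete study on synthetic data: fOCT runs at the
#' requested exposures plus a blank condition, the paired OISI run,
#' the blood-flow velocity index (when the scene has vessels), the
#' dose-response fit over exposures, and the electrophysiology
#' branch (spike trains, PSTH, paired response test, spike-onset
#' latency). All tables are written as CSV, the activation map as
#' TIFF, and every threshold lands in the JSON run report. The run
#' is deterministic given `seed`.
#'
#' @param out_dir output directory.
#' @param protocol an [ins_protocol()].
#' @param scene an [ins_scene()].
#' @param seed integer seed; stage sub-seeds are derived by fixed
#'   offsets.
#' @param config an [ins_config()].
#' @param exposures radiant exposures to run; default the protocol's
#'   set.
#' @param include_blank analyze a blank condition.
#' @param oisi include the OISI branch.
#' @param ephys include the electrophysiology branch.
#' @param depth include depth-resolved courses (at the highest
#'   exposure).
#' @return Invisibly, a list with all in-memory results and the
#'   output paths.
#' @export
run_pipeline <- function(out_dir, protocol, scene, seed,
                         config = ins_config(),
                         exposures = protocol$radiant_exposures,
                         include_blank = TRUE, oisi = TRUE,
                         ephys = TRUE, depth = FALSE) {
  seed <- as.integer(seed)
  tables <- list(); maps <- list()
  latency <- data.frame()
  peaks <- numeric(length(exposures))
  runs <- vector("list", length(exposures))
  emax <- which.max(exposures)
  for (j in seq_along(exposures)) {
    run <- run_foct_pipeline(protocol, scene, exposures[j], seed + j,
                             config, depth = depth && j == emax)
    runs[[j]] <- run
    lat <- onset_delay(run$tc, k = config$onset_k)
    pk <- if (any(is.finite(run$tc$value[run$tc$time_s >= 0])))
      peak_delay(run$tc) else NA_real_
    peaks[j] <- if (any(is.finite(run$tc$value)))
      max(abs(run$tc$value[run$tc$time_s >= 0]), na.rm = TRUE) else NA_real_
    latency <- rbind(latency, data.frame(
      condition = sprintf("foct_%g", exposures[j]),
      onset_s = lat$onset_delay_s, peak_s = pk,
      detected = lat$detected))
    tables[[sprintf("foct_timecourse_%g", exposures[j])]] <-
      tc_to_table(run$tc, condition = sprintf("foct_%g", exposures[j]))
    if (!is.null(run$depth))
      for (b in seq_along(run$depth))
        tables[[sprintf("foct_depth_%d", b)]] <-
          tc_to_table(run$depth[[b]],
                      condition = sprintf("foct_%g", exposures[j]),
                      depth_bin = b)
  }
  if (include_blank) {
    blank <- run_foct_pipeline(protocol, scene, 0, seed + 101L, config,
                               stim = FALSE)
    blat <- if (any(is.finite(blank$tc$value[blank$tc$time_s < 0])))
      onset_delay(blank$tc, k = config$onset_k)
    else list(onset_delay_s = NA_real_, detected = FALSE)
    latency <- rbind(latency, data.frame(
      condition = "blank", onset_s = blat$onset_delay_s,
      peak_s = NA_real_, detected = blat$detected))
    tables$blank_timecourse <- tc_to_table(blank$tc, condition = "blank")
  }
  dose <- NULL
  if (length(unique(exposures)) >= 2 && all(is.finite(peaks))) {
    dose <- dose_response_fit(exposures, peaks)
    tables$dose_response <- data.frame(exposure_j_cm2 = exposures,
                                       peak_drr = peaks)
  }
  if (oisi) {
    os <- simulate_oisi_series(protocol, scene, max(exposures),
                               seed = seed + 201L)
    otc <- oisi_signal(os, roi_px = config$oisi_roi_px)
    olat <- onset_delay(otc, k = config$onset_k)
    latency <- rbind(latency, data.frame(
      condition = "oisi", onset_s = olat$onset_delay_s,
      peak_s = peak_delay(otc), detected = olat$detected))
    tables$oisi_timecourse <- tc_to_table(otc, condition = "oisi")
  }
  if (length(scene$vessels)) {
    vtc <- run_velocity_pipeline(protocol, scene, max(exposures),
                                 seed = seed + 301L,
                                 window = config$decorr_window)
    vlat <- onset_delay(vtc, k = config$onset_k)
    latency <- rbind(latency, data.frame(
      condition = "velocity", onset_s = vlat$onset_delay_s,
      peak_s = peak_delay(vtc), detected = vlat$detected))
    tables$velocity_timecourse <- tc_to_table(vtc, condition = "velocity")
  }
  ep <- NULL
  if (ephys) {
    sp <- simulate_spike_trains(protocol, seed = seed + 401L)
    ps <- build_psth(sp, bin_ms = config$psth_bin_ms,
                     window = c(-protocol$prestim_s, 1))
    test <- ins_response_test(sp)
    slat <- spike_onset_latency(ps, k = config$onset_k)
    ep <- list(psth = ps, test = test, latency = slat)
    tables$psth <- data.frame(bin_start_s = ps$bin_edges_s,
                              count = ps$counts, rate_hz = ps$rate_hz)
    tables$ephys_test <- data.frame(
      comparison = c("stim_vs_pre", "stim_vs_post"),
      t = c(test$t_pre, test$t_post), p = c(test$p_pre, test$p_post))
    latency <- rbind(latency, data.frame(
      condition = "spike_rate", onset_s = slat$onset_delay_s,
      peak_s = NA_real_, detected = slat$detected))
  }
  tables$latency <- latency
  # activation context map from the top-exposure run's masks
  mrun <- runs[[emax]]
  maps$baseline_intensity <- mrun$masks$baseline$Ib
  maps$avascular_mask <- mrun$masks$avascular * 1
  report <- list(package = "insfoct",
                 version = as.character(utils::packageVersion("insfoct")),
                 seed = seed,
                 config = unclass(config),
                 vessel_threshold_used = mrun$masks$vessel_threshold,
                 noise_floor = mrun$masks$noise_floor,
                 exposures = exposures,
                 dose_fit = if (!is.null(dose))
                   dose[c("slope", "intercept", "r")])
  files <- write_results(tables, maps, out_dir, report)
  invisible(list(runs = runs, latency = latency, dose = dose,
                 ephys = ep, files = files, out_dir = out_dir))
}
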