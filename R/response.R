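#' Fractional scattering change dR/R
#'
#' Elementwise fractional change of the intensity relative to the
#' prestimulus baseline, `dR/R(z,x,t) = (I(z,x,t) - Ib(z,x)) /
#' Ib(z,x)`. Pixels with non-positive baseline are set to `NA` and are
#' excluded by all pooling operations (they are additionally removed
#' by the sufficient-intensity mask).
#'
#' @param x a `bm_series` or 3-D array.
#' @param baseline a [compute_baseline()] result.
#' @param trial trial index.
#' @return A 3-D array of the same shape, dimensionless.
#' @export
fractional_change <- function(x, baseline, trial = 1) {
  a <- trial_array(x, trial)
  stopifnot(inherits(baseline, "baseline_stats"))
  d <- dim(a)
  if (!all(dim(baseline$Ib) == d[1:2]))
    stop("baseline shape does not match the series frames")
  Ib <- as.vector(baseline$Ib)
  bad <- Ib <= 0
  dim(a) <- c(d[1] * d[2], d[3])
  a <- (a - Ib) / Ib
  if (any(bad)) a[bad, ] <- NA_real_
  dim(a) <- d
  a
}

# pool one trial's dR/R over eligible pixels.
# pooling = "pixel": a pixel detected significant anywhere in the
#   trial contributes at every frame, with the sign of its dominant
#   label (so the pooled course has a defined prestimulus baseline);
# pooling = "frame": a pixel contributes only at frames covered by a
#   significant run, with that run's label sign (frames with no
#   eligible pixel are NA).
pool_trial <- function(drr, coverage, keep, pooling = c("pixel", "frame")) {
  pooling <- match.arg(pooling)
  d <- dim(drr)
  npx <- d[1] * d[2]; nt <- d[3]
  dim(drr) <- c(npx, nt)
  dim(coverage) <- c(npx, nt)
  keep <- as.vector(keep)
  if (pooling == "pixel") {
    net <- rowSums(coverage)
    any_cov <- rowSums(coverage != 0L) > 0
    elig <- which(keep & any_cov & !is.na(drr[, 1]))
    if (!length(elig))
      return(list(value = rep(NA_real_, nt), n = rep(0, nt)))
    s <- ifelse(net[elig] < 0, -1, 1)   # tie -> positive
    vals <- drr[elig, , drop = FALSE] * s
    list(value = colMeans(vals), n = rep(length(elig), nt))
  } else {
    contrib <- drr * coverage           # label sign applied
    contrib[!keep, ] <- NA_real_
    contrib[coverage == 0L] <- NA_real_
    n <- colSums(!is.na(contrib))
    v <- suppressWarnings(colMeans(contrib, na.rm = TRUE))
    v[n == 0] <- NA_real_
    list(value = v, n = n)
  }
}

#' Mask-filtered, sign-normalized fOCT time course
#'
#' Pools the fractional change over pixels that are significant
#' (adaptive detector), avascular (decorrelation mask) and of
#' sufficient intensity, inverts the contributions of
#' negative-labeled pixels so darkening responses normalize with the
#' positive ones, averages within each frame and then across trials.
#'
#' Two pooling conventions are provided. The default `"pixel"` pools,
#' at every frame, all pixels that carried a significant run anywhere
#' in the trial (each with the sign of its dominant label); this
#' yields a time course with a defined prestimulus baseline, which
#' the onset-latency estimator requires. `"frame"` restricts each
#' pixel's contribution to the frames actually covered by one of its
#' significant runs; frames with no eligible pixel are returned as
#' `NA` and flagged (see attribute `flagged_frames`), not silently
#' zeroed.
#'
#' @param drr_stacks list of per-trial dR/R arrays (or a single
#'   array), from [fractional_change()].
#' @param sig_masks list of per-trial [detect_significant()] results
#'   (or coverage arrays from [significance_coverage()]).
#' @param vascular_mask logical avascular map (TRUE = tissue), a
#'   [build_vascular_mask()] result, or a per-trial list of either;
#'   `NULL` to skip.
#' @param intensity_mask logical sufficient-intensity map or
#'   per-trial list; `NULL` to skip.
#' @param times frame times (s, INS-onset-locked); required for the
#'   time axis.
#' @param pooling `"pixel"` (default) or `"frame"`, see Details.
#' @param condition optional named list of condition labels.
#' @return A [time_course()]; `n_pixels` is the across-trial mean
#'   count of pooled pixels per frame.
#' @export
aggregate_foct <- function(drr_stacks, sig_masks, vascular_mask = NULL,
                           intensity_mask = NULL, times,
                           pooling = c("pixel", "frame"),
                           condition = list()) {
  pooling <- match.arg(pooling)
  if (!is.list(drr_stacks)) drr_stacks <- list(drr_stacks)
  if (inherits(sig_masks, "sig_mask") || is.array(sig_masks))
    sig_masks <- list(sig_masks)
  n_trials <- length(drr_stacks)
  if (length(sig_masks) != n_trials)
    stop("one significance mask per trial is required")
  d <- dim(drr_stacks[[1]])
  get_mask <- function(m, tr, default) {
    if (is.null(m)) return(default)
    if (is.list(m) && !inherits(m, "vascular_mask"))
      m <- m[[min(tr, length(m))]]
    if (inherits(m, "vascular_mask")) m <- m$avascular
    if (!all(dim(m) == d[1:2])) stop("mask shape mismatch")
    m
  }
  all_tissue <- matrix(TRUE, d[1], d[2])
  V <- matrix(0, d[3], n_trials)
  Np <- matrix(0, d[3], n_trials)
  for (tr in seq_len(n_trials)) {
    cov <- sig_masks[[tr]]
    if (inherits(cov, "sig_mask")) cov <- significance_coverage(cov)
    keep <- get_mask(vascular_mask, tr, all_tissue) &
            get_mask(intensity_mask, tr, all_tissue)
    p <- pool_trial(drr_stacks[[tr]], cov, keep, pooling)
    V[, tr] <- p$value
    Np[, tr] <- p$n
  }
  value <- rowMeans(V, na.rm = TRUE)
  value[rowSums(!is.na(V)) == 0] <- NA_real_
  tc <- time_course(time_s = times, value = value,
                    n_pixels = rowMeans(Np), condition = condition)
  attr(tc, "flagged_frames") <- which(!is.finite(value))
  attr(tc, "pooling") <- pooling
  tc
}

#' Depth-resolved fOCT time courses
#'
#' Runs the masked, sign-normalized aggregation of [aggregate_foct()]
#' within consecutive depth slabs under the cortical surface. Bins are
#' half-open `[k * bin_um, (k+1) * bin_um)` in micrometers from the
#' surface (z index 0); the default six 100-um bins cover 0-600 um.
#'
#' @inheritParams aggregate_foct
#' @param bin_um slab thickness in micrometers.
#' @param n_bins number of slabs.
#' @param z_pitch_um depth pixel pitch (um/px).
#' @return A list of [time_course()] objects, one per depth bin, each
#'   labeled with its depth range; slabs with no eligible pixels yield
#'   all-`NA` courses (flagged).
#' @export
depth_resolved <- function(drr_stacks, sig_masks, vascular_mask = NULL,
                           intensity_mask = NULL, times, z_pitch_um,
                           bin_um = 100, n_bins = 6,
                           pooling = c("pixel", "frame")) {
  pooling <- match.arg(pooling)
  if (!is.list(drr_stacks)) drr_stacks <- list(drr_stacks)
  d <- dim(drr_stacks[[1]])
  if (n_bins * bin_um > d[1] * z_pitch_um)
    stop("depth bins exceed the imaged depth")
  z_um <- (seq_len(d[1]) - 1) * z_pitch_um
  out <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    inbin <- z_um >= (b - 1) * bin_um & z_um < b * bin_um
    slab <- matrix(inbin, d[1], d[2])
    imask <- intensity_mask
    if (is.null(imask)) imask <- slab
    else if (is.list(imask) && !inherits(imask, "vascular_mask"))
      imask <- lapply(imask, function(m) m & slab)
    else imask <- imask & slab
    out[[b]] <- aggregate_foct(drr_stacks, sig_masks, vascular_mask,
                               imask, times, pooling,
                               condition = list(depth_bin = b,
                                                depth_um = sprintf("%d-%d",
                                                  (b - 1) * bin_um, b * bin_um)))
  }
  out
}

#' OISI fractional signal in a region of interest
#'
#' Per-frame mean over an ROI of `(I - Ib)/Ib` with `Ib` from the
#' prestimulus window, averaged over trials -- computed like the fOCT
#' signal but without significance, vascular or intensity masks, as
#' appropriate for the camera modality. The default ROI is a 20 x 20
#' pixel box at the frame center (the stimulation locus).
#'
#' @param x an OISI `bm_series`.
#' @param roi logical mask, 2-column index matrix or linear indices;
#'   `NULL` for the default centered `roi_px` x `roi_px` box.
#' @param roi_px default ROI edge length in pixels.
#' @param trials trial indices to average.
#' @return A [time_course()].
#' @export
oisi_signal <- function(x, roi = NULL, roi_px = 20,
                        trials = seq_along(x$data)) {
  stopifnot(inherits(x, "bm_series"))
  d <- dim(x$data[[1]])
  if (is.null(roi)) {
    cy <- round((d[1] + 1) / 2); cx <- round((d[2] + 1) / 2)
    h <- floor(roi_px / 2)
    m <- matrix(FALSE, d[1], d[2])
    m[max(1, cy - h + 1):min(d[1], cy + h),
      max(1, cx - h + 1):min(d[2], cx + h)] <- TRUE
    roi <- m
  }
  idx <- roi_indices(roi, d[1], d[2])
  n_pre <- as.integer(round(x$protocol$prestim_s * x$fps))
  acc <- 0
  for (tr in trials) {
    a <- x$data[[tr]]
    dim(a) <- c(d[1] * d[2], d[3])
    M <- a[idx, , drop = FALSE]
    Ib <- rowMeans(M[, seq_len(n_pre), drop = FALSE])
    acc <- acc + colMeans((M - Ib) / Ib)
  }
  tt <- (seq_len(d[3]) - 1) / x$fps - x$protocol$prestim_s
  time_course(time_s = tt, value = acc / length(trials),
              n_pixels = length(idx),
              condition = list(signal = "oisi", exposure = x$exposure))
}

#' Cross-sectional activation map and significant-pixel count
#'
#' Per-pixel mean dR/R over a time window, restricted to pixels
#' covered by a significant run within that window (after vascular
#' and intensity masking); pixels never significant in the window are
#' `NA`. Also reports the per-trial count of significant pixels in
#' the section.
#'
#' @inheritParams aggregate_foct
#' @param time_window_s numeric `(t0, t1)` window in seconds
#'   (INS-onset-locked, half-open `[t0, t1)`).
#' @return List with `map` (across-trial mean activation map),
#'   `counts` (per-trial significant-pixel counts) and `count` (their
#'   mean).
#' @export
activation_map <- function(drr_stacks, sig_masks, vascular_mask = NULL,
                           intensity_mask = NULL, times, time_window_s) {
  if (!is.list(drr_stacks)) drr_stacks <- list(drr_stacks)
  if (inherits(sig_masks, "sig_mask") || is.array(sig_masks))
    sig_masks <- list(sig_masks)
  d <- dim(drr_stacks[[1]])
  win <- which(times >= time_window_s[1] & times < time_window_s[2])
  if (!length(win)) stop("time window contains no frames")
  all_tissue <- matrix(TRUE, d[1], d[2])
  vm <- vascular_mask
  if (inherits(vm, "vascular_mask")) vm <- vm$avascular
  if (is.null(vm)) vm <- all_tissue
  im <- intensity_mask
  if (is.null(im)) im <- all_tissue
  keep <- as.vector(vm & im)
  npx <- d[1] * d[2]
  msum <- matrix(0, d[1], d[2]); mcnt <- matrix(0, d[1], d[2])
  counts <- numeric(length(drr_stacks))
  for (tr in seq_along(drr_stacks)) {
    cov <- sig_masks[[tr]]
    if (inherits(cov, "sig_mask")) cov <- significance_coverage(cov)
    dim(cov) <- c(npx, d[3])
    drr <- drr_stacks[[tr]]
    dim(drr) <- c(npx, d[3])
    cw <- cov[, win, drop = FALSE] != 0L
    sig_px <- rowSums(cw) > 0 & keep
    counts[tr] <- sum(sig_px)
    if (any(sig_px)) {
      dw <- drr[sig_px, win, drop = FALSE]
      dw[!cw[sig_px, , drop = FALSE]] <- NA_real_
      v <- rowMeans(dw, na.rm = TRUE)
      m <- matrix(0, d[1], d[2])
      m[sig_px] <- v
      msum <- msum + m
      mcnt <- mcnt + matrix(as.numeric(sig_px), d[1], d[2])
    }
  }
  map <- msum / mcnt
  map[mcnt == 0] <- NA_real_
  list(map = map, counts = counts, count = mean(counts))
}
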