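#' Onset latency of a stimulus-locked time course
#'
#' The onset delay is the first time point at or after INS onset
#' (`t = 0`) at which the signal power exceeds its prestimulus
#' baseline by `k` baseline standard deviations, i.e. `power >
#' mean_pre + k * sd_pre`. Signal power is `|value|` by default (it
#' handles positive scattering responses and OISI darkening
#' uniformly); a squared-value option is available. The onset is
#' reported at the sample time of the first crossing, with no
#' sub-sample interpolation, so its resolution is one frame interval.
#'
#' A 3-sigma rule applied frame-wise fires spuriously on isolated
#' noise excursions (about once per ~400 frames for Gaussian noise),
#' which matters for courses with hundreds of samples between `t = 0`
#' and the true response. The crossing is therefore required to be
#' sustained for `sustain` consecutive samples — mirroring the
#' consecutive-frames rule of the adaptive significance detector —
#' and the onset is the first sample of the sustained run. For a
#' noiseless step this reduces to the plain first crossing.
#'
#' @param tc a [time_course()] with a prestimulus window
#'   (`time_s < 0`).
#' @param k threshold multiplier (default 3).
#' @param power `"abs"` (default) or `"square"`.
#' @param sustain consecutive samples the crossing must hold
#'   (default 5); trailing samples that cannot complete a run are
#'   still accepted if all remaining samples exceed the threshold.
#' @return An object of class `latency_result`: list with
#'   `onset_delay_s` (`NA` if never crossed), `detected`,
#'   `baseline_sigma` and `threshold_used`.
#' @export
onset_delay <- function(tc, k = 3, power = c("abs", "square"),
                        sustain = 5) {
  power <- match.arg(power)
  stopifnot(is.data.frame(tc), all(c("time_s", "value") %in% names(tc)))
  p <- if (power == "abs") abs(tc$value) else tc$value^2
  if (!any(tc$time_s < 0)) stop("time course has no prestimulus window")
  pre <- tc$time_s < 0 & is.finite(p)
  if (!any(pre)) {
    # prestim frames exist but none are defined (e.g. no eligible
    # pixels): the baseline is undefined, so nothing can be detected
    return(structure(list(onset_delay_s = NA_real_, detected = FALSE,
                          baseline_sigma = NA_real_,
                          threshold_used = NA_real_, k = k, power = power),
                     class = "latency_result"))
  }
  mu <- mean(p[pre])
  sg <- stats::sd(p[pre])
  if (!is.finite(sg)) sg <- 0
  thr <- mu + k * sg
  sel <- which(tc$time_s >= 0)
  ex <- is.finite(p[sel]) & p[sel] > thr
  n <- length(ex)
  onset_i <- NA_integer_
  for (i in which(ex)) {
    j <- min(i + sustain - 1L, n)
    if (all(ex[i:j])) { onset_i <- i; break }
  }
  detected <- !is.na(onset_i)
  structure(list(onset_delay_s = if (detected) tc$time_s[sel[onset_i]]
                                 else NA_real_,
                 detected = detected, baseline_sigma = sg,
                 threshold_used = thr, k = k, power = power,
                 sustain = sustain),
            class = "latency_result")
}

#' Peak latency of a stimulus-locked time course
#'
#' The time at or after INS onset at which the signal power `|value|`
#' is maximal; ties are broken by the earliest time.
#'
#' @param tc a [time_course()] with samples at `t >= 0`.
#' @return Peak delay in seconds.
#' @export
peak_delay <- function(tc) {
  stopifnot(is.data.frame(tc), all(c("time_s", "value") %in% names(tc)))
  sel <- tc$time_s >= 0 & is.finite(tc$value)
  if (!any(sel)) stop("time course has no finite samples at t >= 0")
  tt <- tc$time_s[sel]
  p <- abs(tc$value[sel])
  tt[which.max(p)]   # which.max returns the earliest maximum
}

#' @export
print.latency_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("onset delay: %.4g ms (threshold %.4g, baseline sigma %.4g)\n",
                1e3 * x$onset_delay_s, x$threshold_used, x$baseline_sigma))
  else cat("onset: not detected\n")
  invisible(x)
}

#' Dose-response linear fit
#'
#' Ordinary least-squares line of the peak response value versus
#' radiant exposure, with Pearson's correlation coefficient.
#'
#' @param exposures radiant exposures (J/cm^2); at least 2 distinct
#'   values.
#' @param peak_values peak response per exposure.
#' @return An object of class `dose_response`: exposures, peaks,
#'   `slope`, `intercept`, `r`, and the underlying `lm` fit.
#' @export
dose_response_fit <- function(exposures, peak_values) {
  if (length(exposures) != length(peak_values))
    stop("exposures and peak_values must have the same length")
  if (length(unique(exposures)) < 2)
    stop("need at least 2 distinct exposures for a fit")
  fit <- stats::lm(peak_values ~ exposures)
  structure(list(exposures = exposures, peak_values = peak_values,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(exposures, peak_values),
                 fit = fit),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose-response fit: slope %.4g per (J/cm2), intercept %.4g, r = %.4f\n",
              x$slope, x$intercept, x$r))
  invisible(x)
}

#' Depth projection view
#'
#' Mean over depth (z) of a volumetric OCT scan, giving the en-face
#' projection image used as the landmark view for coregistration with
#' OISI. The mean (rather than max) projection preserves vessel
#' shadows as landmarks.
#'
#' @param volume a 3-D `(z, x, y)` array.
#' @return An `(x, y)` matrix.
#' @export
projection_view <- function(volume) {
  if (!is.array(volume) || length(dim(volume)) != 3)
    stop("expected a 3-D (z, x, y) volume")
  colMeans(volume)  # averages over the first (depth) dimension
}

#' Translation-search coregistration of OISI and OCT views
#'
#' Exhaustive integer-shift search maximizing Pearson's correlation
#' coefficient between the OISI image and the OCT projection view
#' over their overlap. The optimum shift `(shift_x, shift_y)` is the
#' one for which `oisi[y, x]` best matches
#' `oct[y + shift_y, x + shift_x]`; ties are broken by the smallest
#' shift magnitude, then lexicographically. Translation-only (no
#' rotation or scale).
#'
#' @param oisi_image,oct_projection numeric matrices.
#' @param max_shift search half-range in pixels (both axes).
#' @param min_overlap minimum overlap fraction of the smaller image
#'   for a shift to be admissible.
#' @return List with `shift_x`, `shift_y` and the correlation `r` at
#'   the optimum.
#' @export
coregister <- function(oisi_image, oct_projection, max_shift = 10,
                       min_overlap = 0.5) {
  A <- oisi_image; B <- oct_projection
  if (stats::sd(A) == 0 || stats::sd(B) == 0)
    stop("degenerate (constant) image: correlation undefined")
  na <- dim(A); nb <- dim(B)
  small <- min(prod(na), prod(nb))
  best <- NULL
  for (sy in -max_shift:max_shift) {
    for (sx in -max_shift:max_shift) {
      ya <- max(1, 1 - sy):min(na[1], nb[1] - sy)
      xa <- max(1, 1 - sx):min(na[2], nb[2] - sx)
      if (length(ya) < 2 || length(xa) < 2) next
      if (length(ya) * length(xa) < min_overlap * small) next
      a <- A[ya, xa]; b <- B[ya + sy, xa + sx]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      r <- stats::cor(as.vector(a), as.vector(b))
      cand <- list(shift_x = sx, shift_y = sy, r = r)
      if (is.null(best) || r > best$r + 1e-12 ||
          (abs(r - best$r) <= 1e-12 && better_tie(cand, best)))
        best <- cand
    }
  }
  if (is.null(best)) stop("no admissible shift within max_shift")
  best
}

better_tie <- function(a, b) {
  ma <- a$shift_x^2 + a$shift_y^2
  mb <- b$shift_x^2 + b$shift_y^2
  if (ma != mb) return(ma < mb)
  if (a$shift_x != b$shift_x) return(a$shift_x < b$shift_x)
  a$shift_y < b$shift_y
}
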