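#' Prestimulus baseline statistics
#'
#' Per-pixel mean `Ib(z,x)` and sample standard deviation
#' `sigma_b(z,x)` of the intensity over the prestimulus window (the
#' frames with `t < 0`). The standard deviation uses the N-1
#' denominator.
#'
#' @param x a `bm_series` or a 3-D `(n_z, n_x, n_frames)` array.
#' @param trial trial index when `x` is a multi-trial series.
#' @param n_prestim number of prestimulus frames; inferred from the
#'   series protocol (`prestim_s * fps`) when `x` is a `bm_series`.
#' @return An object of class `baseline_stats`: list with matrices
#'   `Ib` and `sigma_b` and the frame count `N`.
#' @examples
#' a <- array(rep(1:3, each = 4), dim = c(2, 2, 3))
#' b <- compute_baseline(a, n_prestim = 3)
#' b$Ib[1, 1]       # 2
#' b$sigma_b[1, 1]  # 1
#' @export
compute_baseline <- function(x, trial = 1, n_prestim = NULL) {
  a <- trial_array(x, trial)
  if (is.null(n_prestim)) {
    if (!inherits(x, "bm_series"))
      stop("n_prestim is required when x is a plain array")
    n_prestim <- as.integer(round(x$protocol$prestim_s * x$fps))
  }
  if (n_prestim < 2)
    stop("need at least 2 prestimulus frames to estimate the baseline, got ",
         n_prestim)
  d <- dim(a)
  if (n_prestim > d[3]) stop("prestim window exceeds the series length")
  M <- a[, , seq_len(n_prestim), drop = FALSE]
  dim(M) <- c(d[1] * d[2], n_prestim)
  Ib <- rowMeans(M)
  ss <- rowSums((M - Ib)^2)
  sigma <- sqrt(ss / (n_prestim - 1))
  structure(list(Ib = matrix(Ib, d[1], d[2]),
                 sigma_b = matrix(sigma, d[1], d[2]),
                 N = as.integer(n_prestim)),
            class = "baseline_stats")
}

#' Adaptive significant-pixel detection
#'
#' Labels pixel-frames as significant departures from baseline. A
#' pixel is a positive significant signal pixel at frame `ti` iff its
#' intensity exceeds `Ib + k_sigma * sigma_b` in `run_length`
#' consecutive frames starting at `ti` (strict inequality in every
#' frame of the run); negative significance is the analogous
#' condition below `Ib - k_sigma * sigma_b`. Frames closer than
#' `run_length - 1` to the end of the series cannot start a run and
#' are labeled 0. Labels are run-start indexed; use
#' [significance_coverage()] for the frames covered by any run, which
#' is what downstream masking pools over.
#'
#' The detector is invariant to any strictly increasing affine
#' rescaling of the intensities (applied jointly to series and
#' baseline), since both the data and the threshold transform alike.
#'
#' @param x a `bm_series` or 3-D array.
#' @param baseline a [compute_baseline()] result of matching shape.
#' @param k_sigma threshold multiplier (default 3).
#' @param run_length required consecutive frames (default 5).
#' @param trial trial index.
#' @return An object of class `sig_mask`: logical run-start arrays
#'   `pos` and `neg` of the same shape as the data, plus the
#'   parameters used.
#' @seealso [significance_labels()], [significance_coverage()]
#' @export
detect_significant <- function(x, baseline, k_sigma = 3, run_length = 5,
                               trial = 1) {
  a <- trial_array(x, trial)
  stopifnot(inherits(baseline, "baseline_stats"))
  if (k_sigma <= 0) stop("k_sigma must be > 0")
  if (run_length < 1) stop("run_length must be >= 1")
  d <- dim(a)
  if (!all(dim(baseline$Ib) == d[1:2]))
    stop("baseline shape does not match the series frames")
  npx <- d[1] * d[2]; nt <- d[3]
  if (nt < run_length) stop("series shorter than run_length")
  rs <- .sig_runs_cpp(as.numeric(a),
                      as.numeric(baseline$Ib + k_sigma * baseline$sigma_b),
                      as.numeric(baseline$Ib - k_sigma * baseline$sigma_b),
                      d[1], d[2], d[3], as.integer(run_length))
  pos <- rs$pos; neg <- rs$neg
  dim(pos) <- d; dim(neg) <- d
  structure(list(pos = pos, neg = neg, k_sigma = k_sigma,
                 run_length = as.integer(run_length)),
            class = "sig_mask")
}

#' Run-start labels of a significance mask
#'
#' @param mask a [detect_significant()] result.
#' @return Integer array with values +1 (positive run starts at this
#'   pixel-frame), -1, or 0.
#' @export
significance_labels <- function(mask) {
  stopifnot(inherits(mask, "sig_mask"))
  array(1L * mask$pos - 1L * mask$neg, dim = dim(mask$pos))
}

#' Dilate run-start labels to run coverage
#'
#' A pixel-frame is covered if any significant run containing it
#' started, i.e. a run started within the previous `run_length - 1`
#' frames. Positive and negative coverage cannot conflict (a frame
#' cannot lie simultaneously above and below the baseline band).
#'
#' @param mask a [detect_significant()] result.
#' @return Integer array with values +1 (covered by a positive run),
#'   -1, or 0.
#' @export
significance_coverage <- function(mask) {
  stopifnot(inherits(mask, "sig_mask"))
  d <- dim(mask$pos)
  out <- .coverage_cpp(as.logical(mask$pos), as.logical(mask$neg),
                       d[1], d[2], d[3], mask$run_length)
  dim(out) <- d
  out
}

#' Estimate the detector noise floor
#'
#' Mean and standard deviation of the intensity in a designated noise
#' region. By default the deepest `rows_frac` of the depth rows are
#' used (restricted to the prestimulus frames when the series carries
#' a protocol), on the grounds that the OCT signal there has decayed
#' into the detection noise floor; pass a blank (no stimulation)
#' condition for the cleanest estimate.
#'
#' @param x a `bm_series` or 3-D array.
#' @param trial trial index.
#' @param rows optional integer vector of depth rows to use; default
#'   the deepest `rows_frac` rows.
#' @param rows_frac fraction of the deepest rows used when `rows` is
#'   `NULL`.
#' @param prestim_only restrict to prestimulus frames (requires a
#'   `bm_series`); default `TRUE` for one, `FALSE` for plain arrays.
#' @return List with `mean` and `sd` of the noise region.
#' @export
estimate_noise_floor <- function(x, trial = 1, rows = NULL, rows_frac = 0.1,
                                 prestim_only = inherits(x, "bm_series")) {
  a <- trial_array(x, trial)
  d <- dim(a)
  if (is.null(rows)) {
    k <- max(1L, floor(d[1] * rows_frac))
    rows <- (d[1] - k + 1L):d[1]
  }
  frames <- seq_len(d[3])
  if (prestim_only) {
    if (!inherits(x, "bm_series"))
      stop("prestim_only requires a bm_series with a protocol")
    frames <- seq_len(as.integer(round(x$protocol$prestim_s * x$fps)))
  }
  v <- a[rows, , frames]
  list(mean = mean(v), sd = stats::sd(v))
}

#' Sufficient-intensity mask
#'
#' Binary map of pixels whose baseline intensity exceeds the noise
#' floor by `factor` noise standard deviations: `Ib > noise_mean +
#' factor * noise_sigma` (strict). Pixels failing the mask are
#' excluded from fractional-change pooling rather than propagated as
#' NaN.
#'
#' @param baseline a [compute_baseline()] result.
#' @param noise_mean,noise_sigma noise floor statistics, e.g. from
#'   [estimate_noise_floor()] on a blank condition or designated
#'   noise region. Both required; if you have neither a noise region
#'   nor a blank condition, configure one (see
#'   [estimate_noise_floor()]).
#' @param factor threshold multiplier; the default 6 keeps pixels at
#'   least six noise SDs above the floor.
#' @return Logical `n_z x n_x` matrix (TRUE = sufficient intensity).
#' @export
intensity_mask <- function(baseline, noise_mean, noise_sigma, factor = 6) {
  stopifnot(inherits(baseline, "baseline_stats"))
  if (missing(noise_mean) || missing(noise_sigma))
    stop("noise floor statistics are required: estimate them from a ",
         "designated noise region or a blank condition ",
         "(see estimate_noise_floor)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  baseline$Ib > noise_mean + factor * noise_sigma
}
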