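#' Inter-B-scan decorrelation of two frames
#'
#' Per-pixel decorrelation `D = 1 - rho`, where `rho` is the windowed
#' zero-lag normalized cross-correlation of the two intensity frames,
#' \deqn{\rho = \frac{\sum_w A B}{\sqrt{\sum_w A^2 \sum_w B^2}},}
#' with sums over a `window[1] x window[2]` pixel window centered at
#' each pixel (truncated at the frame edges). Moving red blood cells
#' decorrelate the speckle between adjacent B-scans, so `D` highlights
#' vessels; its magnitude indexes flow velocity. `D` is clipped to
#' [0, 1], is invariant to a global intensity gain, and is defined as
#' 0 where both windows have zero energy.
#'
#' @param frame_a,frame_b intensity matrices of identical shape.
#' @param window integer vector `(wz, wx)`, default 3 x 3.
#' @return A `decorr_map`: numeric matrix in [0, 1] with the window in
#'   an attribute.
#' @export
interframe_decorrelation <- function(frame_a, frame_b, window = c(3, 3)) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames must have the same shape")
  if (any(window < 1)) stop("window must be at least 1 x 1")
  sAB <- boxsum_zx(frame_a * frame_b, window[1], window[2])
  sAA <- boxsum_zx(frame_a * frame_a, window[1], window[2])
  sBB <- boxsum_zx(frame_b * frame_b, window[1], window[2])
  den <- sqrt(sAA * sBB)
  rho <- ifelse(den > 0, sAB / den, 1)  # zero-energy window -> D = 0
  D <- pmin(pmax(1 - rho, 0), 1)
  structure(D, window = as.integer(window), class = c("decorr_map", class(D)))
}

#' Decorrelation angiogram of a B-M series
#'
#' One decorrelation map per adjacent frame pair (inter-B-scan lag of
#' one frame), plus the temporal-mean map used for display and for
#' vessel binarization.
#'
#' @param x a `bm_series` or 3-D array (>= 2 frames).
#' @param window decorrelation window `(wz, wx)`.
#' @param trial trial index.
#' @return An object of class `angiogram`: list with `maps` (a
#'   `(n_z, n_x, n_frames - 1)` array, map `k` for frames `k, k+1`),
#'   `mean_map`, and `window`.
#' @export
angiogram_series <- function(x, window = c(3, 3), trial = 1) {
  a <- trial_array(x, trial)
  d <- dim(a)
  if (d[3] < 2) stop("need at least 2 frames for an angiogram")
  D <- .decorr_series_cpp(as.numeric(a), d[1], d[2], d[3],
                          as.integer(window[1]), as.integer(window[2]))
  dim(D) <- c(d[1] * d[2], d[3] - 1L)
  mean_map <- matrix(rowMeans(D), d[1], d[2])
  dim(D) <- c(d[1], d[2], d[3] - 1L)
  structure(list(maps = D, mean_map = mean_map,
                 window = as.integer(window)),
            class = "angiogram")
}

#' Binary avascular mask from decorrelation maps
#'
#' Each map is binarized (vessel where `D > threshold`); optionally
#' every pixel below a detected vessel pixel, down to the bottom of
#' its A-line, is also marked vessel (the projection/tail artifact of
#' the vessel shadow). The per-frame avascular mask is the complement,
#' and the final mask is the logical AND (intersection) over all
#' frames, so a vessel detected in any single frame is excluded from
#' the final avascular mask.
#'
#' @param maps an `angiogram`, a 3-D array of decorrelation maps, a
#'   list of matrices, or a single matrix.
#' @param threshold binarization threshold for `D`; `NULL` (default)
#'   selects it by Otsu's method on the temporal-mean map. If every
#'   map is (numerically) zero, no vessels are detected.
#' @param tail_extend extend vessel labels to the bottom of each
#'   A-line (default `TRUE`).
#' @return An object of class `vascular_mask`: list with the logical
#'   `avascular` map (TRUE = tissue), the `vessel` complement, and the
#'   `threshold` used.
#' @export
build_vascular_mask <- function(maps, threshold = NULL, tail_extend = TRUE) {
  if (inherits(maps, "angiogram")) {
    M3 <- maps$maps; mean_map <- maps$mean_map
  } else {
    if (is.list(maps)) maps <- array(unlist(maps),
                                     dim = c(dim(maps[[1]]), length(maps)))
    if (is.matrix(maps)) maps <- array(maps, dim = c(dim(maps), 1))
    M3 <- maps
    mean_map <- apply(M3, c(1, 2), mean)
  }
  dmax <- reduce_max3(M3)
  if (is.null(threshold)) {
    if (max(dmax) <= 1e-12) {
      threshold <- Inf    # degenerate: static data, no vessels
    } else {
      threshold <- EBImage::otsu(mean_map, range = c(0, 1))
    }
  }
  # union of per-frame vessel masks == pixels exceeding the threshold
  # in any frame; tail extension commutes with the union since it is a
  # columnwise downward closure
  vessel <- dmax > threshold
  if (tail_extend && any(vessel)) {
    cm <- apply(vessel, 2, cummax)
    vessel <- vessel | (cm > 0)
  }
  structure(list(avascular = !vessel, vessel = vessel,
                 threshold = threshold),
            class = "vascular_mask")
}

#' Blood-flow velocity index time course
#'
#' Mean adjacent-frame decorrelation over a region of interest, one
#' value per frame pair (stamped at the later frame's time), averaged
#' over trials. The decorrelation value serves as a relative index of
#' red-blood-cell velocity.
#'
#' @param x a `bm_series`.
#' @param roi logical `n_z x n_x` mask, 2-column (z, x) index matrix,
#'   or linear indices; must be non-empty and inside the frame.
#' @param window decorrelation window.
#' @param trials trial indices to average (default all).
#' @return A [time_course()] of decorrelation values.
#' @export
velocity_index <- function(x, roi, window = c(3, 3),
                           trials = seq_along(x$data)) {
  stopifnot(inherits(x, "bm_series"))
  d <- dim(x$data[[1]])
  idx <- roi_indices(roi, d[1], d[2])
  npx <- d[1] * d[2]
  acc <- NULL
  for (tr in trials) {
    ang <- angiogram_series(x, window = window, trial = tr)
    M <- ang$maps
    dim(M) <- c(npx, d[3] - 1L)
    v <- colMeans(M[idx, , drop = FALSE])
    acc <- if (is.null(acc)) v else acc + v
  }
  tt <- (seq_len(d[3]) - 1) / x$fps - x$protocol$prestim_s
  time_course(time_s = tt[-1], value = acc / length(trials),
              n_pixels = length(idx),
              condition = list(signal = "velocity_index",
                               exposure = x$exposure))
}

#' Decorrelation-velocity calibration curve
#'
#' Mean decorrelation of each flow-phantom series versus its
#' programmed velocity, for verifying that the decorrelation value
#' increases monotonically with velocity over the calibrated range.
#'
#' @param phantom_series list of single-trial `bm_series` from
#'   [simulate_flow_phantom()] (or comparable), each carrying
#'   `$velocity_mm_s`.
#' @param window decorrelation window.
#' @param border pixels to trim from each frame edge before averaging
#'   (excludes truncated windows).
#' @return Data frame with columns `velocity_mm_s` and `mean_D`.
#' @export
decorrelation_velocity_curve <- function(phantom_series, window = c(3, 3),
                                         border = 2) {
  if (length(phantom_series) < 2)
    stop("need at least 2 velocities for a calibration curve")
  out <- data.frame(velocity_mm_s = numeric(0), mean_D = numeric(0))
  for (s in phantom_series) {
    ang <- angiogram_series(s, window = window, trial = 1)
    d <- dim(ang$maps)
    zi <- (1 + border):(d[1] - border)
    xi <- (1 + border):(d[2] - border)
    out <- rbind(out, data.frame(velocity_mm_s = s$velocity_mm_s,
                                 mean_D = mean(ang$maps[zi, xi, ])))
  }
  out
}

#' @export
print.vascular_mask <- function(x, ...) {
  cat(sprintf("vascular mask: %d vessel/tail px, %d tissue px (threshold %.4g)\n",
              sum(x$vessel), sum(x$avascular), x$threshold))
  invisible(x)
}
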