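# internal numerics shared across modules

# per-column cumulative sums along the first dimension of an array,
# computed on the flat vector (O(n), no apply loop)
cumsum_dim1 <- function(a) {
  d <- dim(a)
  n1 <- d[1]
  ncols <- prod(d) / n1
  cs <- cumsum(as.vector(a))
  ends <- cs[n1 * seq_len(ncols)]
  off <- rep(c(0, ends[-ncols]), each = n1)
  array(cs - off, dim = d)
}

# windowed (box) sum along the first dimension of a (z, x, t) array,
# window size w centered (truncated at the edges)
boxsum_dim1 <- function(a, w) {
  d <- dim(a)
  n1 <- d[1]
  h1 <- (w - 1L) %/% 2L           # rows above
  h2 <- w - 1L - h1               # rows below
  P <- cumsum_dim1(a)
  # pad a zero slab on top so index 1 means "sum of nothing"
  Ppad <- array(0, dim = c(n1 + 1L, d[2], d[3]))
  Ppad[-1, , ] <- P
  hi <- pmin(seq_len(n1) + h2, n1) + 1L
  lo <- pmax(seq_len(n1) - h1 - 1L, 0L) + 1L
  out <- Ppad[hi, , , drop = FALSE] - Ppad[lo, , , drop = FALSE]
  dim(out) <- d
  out
}

# 2-D box sum over dims 1 and 2 of a matrix or (z, x, t) array
boxsum_zx <- function(a, wz, wx) {
  d <- dim(a)
  was_mat <- length(d) == 2
  if (was_mat) dim(a) <- c(d, 1L)
  b <- boxsum_dim1(a, wz)
  b <- aperm(b, c(2, 1, 3))
  b <- boxsum_dim1(b, wx)
  b <- aperm(b, c(2, 1, 3))
  if (was_mat) dim(b) <- d
  b
}

# elementwise max over the third dimension
reduce_max3 <- function(a) {
  d <- dim(a)
  out <- a[, , 1]
  if (d[3] > 1) for (k in 2:d[3]) out <- pmax(out, a[, , k])
  out
}

#' Stimulus-locked time course container
#'
#' A data frame with columns `time_s` (seconds relative to INS onset),
#' `value`, and `n_pixels` (pixels pooled per frame), plus condition
#' metadata in attributes. All aggregation operations return this
#' class.
#'
#' @param time_s,value,n_pixels column vectors.
#' @param condition named list of condition labels (exposure, depth
#'   bin, roi id, ...).
#' @return A `time_course` data frame.
#' @export
time_course <- function(time_s, value, n_pixels = NA_real_,
                        condition = list()) {
  tc <- data.frame(time_s = time_s, value = value, n_pixels = n_pixels)
  class(tc) <- c("time_course", "data.frame")
  attr(tc, "condition") <- condition
  tc
}

#' @export
print.time_course <- function(x, ...) {
  cnd <- attr(x, "condition")
  cat(sprintf("time course: %d frames, t in [%.3g, %.3g] s", nrow(x),
              min(x$time_s), max(x$time_s)))
  if (length(cnd))
    cat(" (", paste(names(cnd), unlist(cnd), sep = "=", collapse = ", "), ")",
        sep = "")
  cat("\n")
  ok <- is.finite(x$value)
  if (any(ok))
    cat(sprintf("  value range [%.4g, %.4g], %d undefined frame(s)\n",
                min(x$value[ok]), max(x$value[ok]), sum(!ok)))
  invisible(x)
}

# resolve a trial's 3-D data array from a bm_series or a plain array
trial_array <- function(x, trial = 1) {
  if (inherits(x, "bm_series")) x$data[[trial]]
  else if (is.array(x) && length(dim(x)) == 3) x
  else stop("expected a bm_series or a 3-D array")
}

# resolve an roi argument (logical matrix or 2-column index matrix or
# linear indices) to linear indices into an nz x nx frame
roi_indices <- function(roi, nz, nx) {
  if (is.logical(roi)) {
    if (!all(dim(roi) == c(nz, nx))) stop("roi mask has wrong dimensions")
    idx <- which(roi)
  } else if (is.matrix(roi) && ncol(roi) == 2) {
    if (any(roi[, 1] < 1 | roi[, 1] > nz | roi[, 2] < 1 | roi[, 2] > nx))
      stop("roi indices outside the frame")
    idx <- (roi[, 2] - 1L) * nz + roi[, 1]
  } else {
    idx <- as.integer(roi)
    if (any(idx < 1 | idx > nz * nx)) stop("roi indices outside the frame")
  }
  if (length(idx) == 0) stop("empty roi")
  idx
}
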