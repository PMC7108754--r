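#' Threshold-crossing spike detection
#'
#' Detects spikes at negative-going crossings of the voltage
#' threshold (extracellular spikes are negative deflections; the
#' working threshold is -41 mV): a spike is stamped at the first
#' sample at or below threshold after the trace was above it.
#' Subsequent crossings within the refractory window are suppressed
#' to prevent double counting. No spike sorting is performed;
#' single-unit and multi-unit activity are treated alike.
#'
#' @param voltage_mv calibrated voltage trace in millivolts.
#' @param fs_hz sampling rate (Hz); the recording default is 30 kHz.
#' @param threshold_mv spike threshold in mV (default -41).
#' @param refractory_ms dead time after each detected spike (ms).
#' @param t0_s time of the first sample, in INS-onset-locked seconds.
#' @return Numeric vector of spike times (s), sorted ascending.
#' @export
detect_spikes <- function(voltage_mv, fs_hz = 30000, threshold_mv = -41,
                          refractory_ms = 1, t0_s = 0) {
  if (!is.numeric(voltage_mv)) stop("voltage trace must be numeric (mV)")
  n <- length(voltage_mv)
  if (n < 2) return(numeric(0))
  cross <- which(voltage_mv[-1] < threshold_mv &
                 voltage_mv[-n] >= threshold_mv) + 1L
  if (!length(cross)) return(numeric(0))
  refr <- refractory_ms * 1e-3 * fs_hz
  keep <- cross[1]
  last <- cross[1]
  for (i in cross[-1]) {
    if (i - last >= refr) { keep <- c(keep, i); last <- i }
  }
  (keep - 1) / fs_hz + t0_s
}

#' Peristimulus time histogram
#'
#' Bins INS-onset-locked spike timestamps into half-open bins
#' `[edge, edge + bin)`, summing counts over trials, and converts to
#' rate as `counts / (n_trials * bin_width)`.
#'
#' @param spikes a `spike_data` object (see
#'   [simulate_spike_trains()]) or a list of per-trial timestamp
#'   vectors.
#' @param bin_ms bin width in milliseconds; spike-onset analysis uses
#'   1-ms bins.
#' @param window analysis window `(t0, t1)` in seconds; defaults to
#'   the protocol trial bounds when available.
#' @return An object of class `psth`: `bin_edges_s` (left edges),
#'   `counts`, `rate_hz`, `bin_ms`, `n_trials`.
#' @export
build_psth <- function(spikes, bin_ms, window = NULL) {
  if (bin_ms <= 0) stop("bin_ms must be positive")
  trials <- if (inherits(spikes, "spike_data")) spikes$trials else spikes
  if (is.null(window)) {
    if (inherits(spikes, "spike_data")) {
      p <- spikes$protocol
      window <- c(-p$prestim_s, p$stim_s + p$poststim_s)
    } else stop("window is required when spikes carry no protocol")
  }
  bw <- bin_ms * 1e-3
  nb <- floor((window[2] - window[1]) / bw + 1e-9)
  edges <- window[1] + (seq_len(nb) - 1) * bw
  counts <- integer(nb)
  for (ts in trials) {
    ts <- ts[ts >= window[1] & ts < window[1] + nb * bw]
    if (length(ts))
      counts <- counts + tabulate(floor((ts - window[1]) / bw) + 1L, nbins = nb)
  }
  structure(list(bin_edges_s = edges, counts = counts,
                 rate_hz = counts / (length(trials) * bw),
                 bin_ms = bin_ms, n_trials = length(trials)),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %g ms over %d trials, %d spikes total\n",
              length(x$counts), x$bin_ms, x$n_trials, sum(x$counts)))
  invisible(x)
}

#' Paired test of the INS-evoked spike-rate change
#'
#' Per-trial spike counts in the stimulation window are compared with
#' the counts in a pre-INS and a post-INS window of equal length by
#' paired two-tailed t-tests. Counts (not rates) are the paired
#' variable; the two are equivalent up to a constant scale. A
#' zero-variance set of differences with a nonzero mean leaves the
#' t-statistic undefined and is flagged; identical counts in every
#' trial give `t = 0, p = 1`.
#'
#' @param spikes a `spike_data` or list of per-trial timestamp
#'   vectors (>= 2 trials).
#' @param stim_window,pre_window,post_window half-open `[a, b)`
#'   windows in INS-onset-locked seconds.
#' @return List with `t_pre`, `p_pre`, `t_post`, `p_post`, the
#'   per-trial `counts` data frame, and `flags` naming any degenerate
#'   comparisons.
#' @export
ins_response_test <- function(spikes, stim_window = c(0, 0.5),
                              pre_window = c(-0.5, 0),
                              post_window = c(0.5, 1.0)) {
  trials <- if (inherits(spikes, "spike_data")) spikes$trials else spikes
  if (length(trials) < 2) stop("need at least 2 trials")
  cnt <- function(w) vapply(trials, function(ts)
    sum(ts >= w[1] & ts < w[2]), numeric(1))
  stim <- cnt(stim_window); pre <- cnt(pre_window); post <- cnt(post_window)
  paired <- function(x, y) {
    d <- x - y
    if (stats::sd(d) == 0) {
      if (all(d == 0)) return(list(t = 0, p = 1, flag = NA_character_))
      return(list(t = sign(mean(d)) * Inf, p = NA_real_,
                  flag = "zero-variance differences"))
    }
    tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
    list(t = unname(tt$statistic), p = tt$p.value, flag = NA_character_)
  }
  a <- paired(stim, pre)
  b <- paired(stim, post)
  flags <- stats::na.omit(c(pre = a$flag, post = b$flag))
  list(t_pre = a$t, p_pre = a$p, t_post = b$t, p_post = b$p,
       counts = data.frame(trial = seq_along(trials), stim = stim,
                           pre = pre, post = post),
       flags = as.character(flags))
}

#' Spike-rate onset latency from a PSTH
#'
#' The left edge of the first bin at or after INS onset whose rate
#' exceeds the prestimulus mean by `k` prestimulus standard
#' deviations. With 1-ms bins this resolves the ~millisecond latency
#' of direct neural activation.
#'
#' @param psth a [build_psth()] result with prestimulus bins.
#' @param k threshold multiplier (default 3).
#' @return A `latency_result` (see [onset_delay()]); `detected =
#'   FALSE` when no bin crosses.
#' @export
spike_onset_latency <- function(psth, k = 3) {
  stopifnot(inherits(psth, "psth"))
  pre <- psth$bin_edges_s < 0
  if (!any(pre)) stop("PSTH has no prestimulus bins")
  mu <- mean(psth$rate_hz[pre])
  sg <- stats::sd(psth$rate_hz[pre])
  if (!is.finite(sg)) sg <- 0
  thr <- mu + k * sg
  post <- which(psth$bin_edges_s >= 0 & psth$rate_hz > thr)
  detected <- length(post) > 0
  structure(list(onset_delay_s = if (detected) psth$bin_edges_s[post[1]]
                                 else NA_real_,
                 detected = detected, baseline_sigma = sg,
                 threshold_used = thr, k = k, power = "rate"),
            class = "latency_result")
}
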