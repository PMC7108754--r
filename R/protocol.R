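#' Acquisition protocol for a stimulus-locked imaging run
#'
#' Bundles the trial timing, frame rates, stimulation pulse-train
#' parameters and frame geometry of a coregistered INS--fOCT--OISI
#' acquisition. The defaults reproduce the standard protocol used
#' throughout the package: each trial is a 1-s prestimulus period,
#' 0.5 s of INS (250-us pulses at 200 Hz, i.e. 100 pulses), and an
#' 18.5-s poststimulus recovery, repeated over 15 trials, with the OCT
#' B-frame rate at 100 fps and the OISI camera at 20 fps (240/60 fps
#' for high-rate temporal analysis).
#'
#' Time is always expressed relative to INS onset: frame \eqn{k}
#' (1-based) of a modality running at \eqn{f} fps is stamped
#' \eqn{t_k = (k-1)/f - \mathrm{prestim}}, so the prestimulus window is
#' \eqn{[-1, 0)} s under the defaults.
#'
#' @param prestim_s,stim_s,poststim_s trial phase durations in seconds.
#' @param n_trials number of repeated trials.
#' @param oct_fps OCT B-frame rate (frames/s); 100 by default, 240 for
#'   temporal analysis.
#' @param oisi_fps OISI camera frame rate (frames/s); 20 by default,
#'   60 for temporal analysis.
#' @param pulse_width_us INS pulse width in microseconds.
#' @param pulse_rate_hz INS pulse repetition rate in Hz. The pulse
#'   count `pulse_rate_hz * stim_s` must be a whole number.
#' @param radiant_exposures radiant exposures available in the run, in
#'   J/cm^2 per pulse.
#' @param z_pitch_um,x_pitch_um pixel pitch in depth and lateral
#'   direction, micrometers per pixel.
#' @param n_z,n_x frame size in pixels (depth x lateral).
#'
#' @return An object of class `ins_protocol` (a validated list).
#' @examples
#' p <- ins_protocol()
#' n_pulses(p)            # 100
#' n_frames(p, "oct")     # 2000 frames in a 20-s trial at 100 fps
#' @export
ins_protocol <- function(prestim_s = 1, stim_s = 0.5, poststim_s = 18.5,
                         n_trials = 15, oct_fps = 100, oisi_fps = 20,
                         pulse_width_us = 250, pulse_rate_hz = 200,
                         radiant_exposures = c(0.3, 0.5, 0.7, 1.0),
                         z_pitch_um = 10, x_pitch_um = 10,
                         n_z = 64, n_x = 64) {
  p <- list(prestim_s = prestim_s, stim_s = stim_s, poststim_s = poststim_s,
            n_trials = as.integer(n_trials), oct_fps = oct_fps,
            oisi_fps = oisi_fps, pulse_width_us = pulse_width_us,
            pulse_rate_hz = pulse_rate_hz,
            radiant_exposures = radiant_exposures,
            z_pitch_um = z_pitch_um, x_pitch_um = x_pitch_um,
            n_z = as.integer(n_z), n_x = as.integer(n_x))
  class(p) <- "ins_protocol"
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "ins_protocol"))
  durs <- c(prestim_s = p$prestim_s, stim_s = p$stim_s, poststim_s = p$poststim_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all trial phase durations must be positive, got: ",
         paste(sprintf("%s=%g", names(durs), durs), collapse = ", "))
  if (p$n_trials < 1) stop("n_trials must be >= 1")
  if (p$oct_fps <= 0 || p$oisi_fps <= 0) stop("frame rates must be positive")
  np <- p$pulse_rate_hz * p$stim_s
  if (abs(np - round(np)) > 1e-9)
    stop("pulse_rate_hz * stim_s must be a whole pulse count, got ", np)
  if (p$n_z < 1 || p$n_x < 1) stop("frame size must be at least 1x1")
  if (any(p$radiant_exposures < 0)) stop("radiant exposures must be >= 0")
  invisible(p)
}

#' @rdname ins_protocol
#' @param p an `ins_protocol`.
#' @export
n_pulses <- function(p) as.integer(round(p$pulse_rate_hz * p$stim_s))

#' @rdname ins_protocol
#' @param modality `"oct"` or `"oisi"`, selecting the frame rate.
#' @export
n_frames <- function(p, modality = c("oct", "oisi")) {
  modality <- match.arg(modality)
  fps <- if (modality == "oct") p$oct_fps else p$oisi_fps
  as.integer(round(trial_duration(p) * fps))
}

#' @rdname ins_protocol
#' @export
trial_duration <- function(p) p$prestim_s + p$stim_s + p$poststim_s

#' Frame timestamps relative to INS onset
#'
#' @param p an `ins_protocol`.
#' @param modality `"oct"` or `"oisi"`.
#' @return Numeric vector of frame times in seconds; `t = 0` is INS
#'   onset, prestimulus times are negative.
#' @export
frame_times <- function(p, modality = c("oct", "oisi")) {
  modality <- match.arg(modality)
  fps <- if (modality == "oct") p$oct_fps else p$oisi_fps
  (seq_len(n_frames(p, modality)) - 1) / fps - p$prestim_s
}

#' @export
print.ins_protocol <- function(x, ...) {
  cat("INS acquisition protocol\n")
  cat(sprintf("  trial: %g s prestim + %g s INS + %g s poststim (%d trials)\n",
              x$prestim_s, x$stim_s, x$poststim_s, x$n_trials))
  cat(sprintf("  INS: %g-us pulses at %g Hz (%d pulses/trial), exposures {%s} J/cm2\n",
              x$pulse_width_us, x$pulse_rate_hz, n_pulses(x),
              paste(x$radiant_exposures, collapse = ", ")))
  cat(sprintf("  OCT %g fps (%d frames/trial), OISI %g fps (%d frames/trial)\n",
              x$oct_fps, n_frames(x, "oct"), x$oisi_fps, n_frames(x, "oisi")))
  cat(sprintf("  frame %d x %d px at %g x %g um pitch\n",
              x$n_z, x$n_x, x$z_pitch_um, x$x_pitch_um))
  invisible(x)
}
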