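#' Stimulus-locked fractional-change response template
#'
#' Parameterizes the programmed fractional intensity change of an
#' activated pixel as a function of time relative to INS onset. The
#' template is exactly zero before `onset_delay_s`, rises to a maximum
#' of `peak_amplitude` (at the reference exposure of 1 J/cm^2) at
#' `peak_delay_s`, and recovers exponentially afterwards with time
#' constant `decay_tau_s`.
#'
#' The rise is modeled as the sum of a fast saturating component and a
#' slower accumulating component,
#' \deqn{r(u) = \tfrac12 u^{1/4} + \tfrac12 u^{3}, \quad
#'       u = (t - t_\mathrm{on}) / (t_\mathrm{peak} - t_\mathrm{on}),}
#' so the signal departs baseline steeply at the programmed onset
#' (making the onset well defined for a threshold-crossing estimator)
#' while still attaining a non-flat maximum exactly at the programmed
#' peak time. Peak amplitude scales linearly with radiant exposure via
#' `amplitude_vs_exposure_slope` (amplitude = slope * exposure), i.e.
#' the template amplitude at exposure E is `slope * E`.
#'
#' Amplitudes are calibrated at the reporting time rather than at the
#' template maximum: the reference trial-mean responses are defined at
#' `t = 0.5` s (2.5% for fOCT, 0.12% for OISI, both at 1 J/cm^2 and
#' both just before the respective peak times), so by default
#' `peak_amplitude` is derived such that the programmed fractional
#' change at `anchor_t_s` equals `anchor_value`. Supplying
#' `peak_amplitude` directly overrides the anchoring.
#'
#' Defaults are the package's reference fOCT response: onset 30 ms,
#' peak 528 ms, 2.5% at 0.5 s and 1 J/cm^2, scattering increase
#' (`sign = +1`). `oisi_template()` returns the matching OISI darkening
#' response (onset 40 ms, peak 533 ms, 0.12% at 0.5 s, `sign = -1`).
#'
#' @param onset_delay_s seconds after INS onset before the fractional
#'   change departs baseline.
#' @param peak_delay_s seconds after INS onset at which the magnitude
#'   of the fractional change is maximal; must exceed `onset_delay_s`.
#' @param peak_amplitude dimensionless peak fraction at 1 J/cm^2;
#'   `NULL` (default) derives it from the anchor.
#' @param anchor_t_s,anchor_value calibration point: the unsigned
#'   fractional change at `anchor_t_s` (s after INS onset) is
#'   `anchor_value` at 1 J/cm^2. Ignored when `peak_amplitude` is
#'   given.
#' @param decay_tau_s exponential recovery time constant (s).
#' @param sign +1 for a scattering increase, -1 for darkening.
#' @param amplitude_vs_exposure_slope fraction per (J/cm^2); defaults
#'   to `peak_amplitude` so that amplitude(1 J/cm^2) = `peak_amplitude`.
#' @return An object of class `response_template`.
#' @seealso [template_eval()]
#' @examples
#' tpl <- response_template()
#' template_eval(tpl, c(-0.5, 0.02, 0.5, 5), exposure = 1)
#' @export
response_template <- function(onset_delay_s = 0.030, peak_delay_s = 0.528,
                              peak_amplitude = NULL,
                              anchor_t_s = 0.5, anchor_value = 0.025,
                              decay_tau_s = 2, sign = 1L,
                              amplitude_vs_exposure_slope = peak_amplitude) {
  if (!(onset_delay_s >= 0 && onset_delay_s < peak_delay_s))
    stop("need 0 <= onset_delay_s < peak_delay_s")
  if (decay_tau_s <= 0) stop("decay_tau_s must be positive")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (is.null(peak_amplitude)) {
    u <- (anchor_t_s - onset_delay_s) / (peak_delay_s - onset_delay_s)
    shape <- if (u >= 1) exp(-(anchor_t_s - peak_delay_s) / decay_tau_s)
             else if (u <= 0) stop("anchor_t_s precedes the onset")
             else 0.5 * u^0.25 + 0.5 * u^3
    peak_amplitude <- anchor_value / shape
  }
  if (is.null(amplitude_vs_exposure_slope))
    amplitude_vs_exposure_slope <- peak_amplitude
  structure(list(onset_delay_s = onset_delay_s, peak_delay_s = peak_delay_s,
                 peak_amplitude = peak_amplitude, decay_tau_s = decay_tau_s,
                 sign = as.integer(sign),
                 amplitude_vs_exposure_slope = amplitude_vs_exposure_slope),
            class = "response_template")
}

#' @rdname response_template
#' @export
oisi_template <- function(onset_delay_s = 0.040, peak_delay_s = 0.533,
                          peak_amplitude = NULL,
                          anchor_t_s = 0.5, anchor_value = 0.0012,
                          decay_tau_s = 2, sign = -1L,
                          amplitude_vs_exposure_slope = peak_amplitude) {
  response_template(onset_delay_s, peak_delay_s, peak_amplitude,
                    anchor_t_s, anchor_value, decay_tau_s, sign,
                    amplitude_vs_exposure_slope)
}

#' Evaluate a response template
#'
#' Returns the signed programmed fractional change at times `t`
#' (seconds relative to INS onset) for a given radiant exposure.
#'
#' @param tpl a [response_template()].
#' @param t numeric vector of times (s, INS-onset-locked).
#' @param exposure radiant exposure in J/cm^2.
#' @return Numeric vector: `sign * amplitude(exposure) * shape(t)`,
#'   exactly 0 for `t < onset_delay_s`.
#' @export
template_eval <- function(tpl, t, exposure = 1) {
  stopifnot(inherits(tpl, "response_template"))
  amp <- tpl$amplitude_vs_exposure_slope * exposure
  out <- numeric(length(t))
  rise <- t >= tpl$onset_delay_s & t <= tpl$peak_delay_s
  u <- (t[rise] - tpl$onset_delay_s) / (tpl$peak_delay_s - tpl$onset_delay_s)
  out[rise] <- 0.5 * u^0.25 + 0.5 * u^3
  dec <- t > tpl$peak_delay_s
  out[dec] <- exp(-(t[dec] - tpl$peak_delay_s) / tpl$decay_tau_s)
  tpl$sign * amp * out
}

#' @export
print.response_template <- function(x, ...) {
  cat(sprintf(paste0("response template: onset %g ms, peak %g ms, ",
                     "amplitude %s%g%% at 1 J/cm2, decay tau %g s\n"),
              1e3 * x$onset_delay_s, 1e3 * x$peak_delay_s,
              if (x$sign > 0) "+" else "-", 100 * x$peak_amplitude,
              x$decay_tau_s))
  invisible(x)
}

# Hemodynamic (blood-flow velocity) response: relative velocity
# multiplier applied to a vessel's scatterer speed. Step increase
# `amp * exposure` starting `onset_delay_s` after INS onset, plateau to
# `plateau_end_s`, then exponential recovery.
#' Hemodynamic velocity-response profile
#'
#' Relative increase of a vessel's scatterer velocity in response to
#' INS: velocity(t) = v0 * (1 + hemo(t)). The default is a 50% step
#' increase (at 1 J/cm^2, scaling linearly with exposure) with the
#' functional-hyperemia onset latency of 1.0 s, held to `plateau_end_s`
#' and recovering exponentially.
#'
#' @param onset_delay_s latency of the velocity increase after INS
#'   onset (s).
#' @param amp relative velocity increase at 1 J/cm^2 (0.5 = +50%).
#' @param plateau_end_s end of the plateau (s after INS onset).
#' @param decay_tau_s recovery time constant (s).
#' @return A function `f(t, exposure)` returning the multiplier - 1.
#' @export
hemo_profile <- function(onset_delay_s = 1.0, amp = 0.5,
                         plateau_end_s = 6, decay_tau_s = 3) {
  force(onset_delay_s); force(amp); force(plateau_end_s); force(decay_tau_s)
  f <- function(t, exposure = 1) {
    out <- numeric(length(t))
    on <- t >= onset_delay_s & t <= plateau_end_s
    out[on] <- amp * exposure
    dec <- t > plateau_end_s
    out[dec] <- amp * exposure * exp(-(t[dec] - plateau_end_s) / decay_tau_s)
    out
  }
  attr(f, "onset_delay_s") <- onset_delay_s
  attr(f, "amp") <- amp
  f
}
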