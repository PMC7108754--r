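#' Simulate a B-M-mode OCT intensity series with known ground truth
#'
#' Generates `protocol$n_trials` stacks of shape
#' `(n_z, n_x, frames/trial)` emulating a repeated-B-scan (B-M mode)
#' functional OCT recording. Static tissue carries a multiplicative
#' exponential speckle factor drawn once per trial, so its
#' frame-to-frame correlation is high (perturbed only by additive
#' detector noise). Vessel pixels contain moving scatterers: each
#' frame, a vessel pixel's speckle factor is redrawn with probability
#' `min(1, v * dt / beam_width)`, which makes adjacent-frame
#' decorrelation increase monotonically with the programmed velocity
#' up to saturation. Tail-artifact pixels beneath each vessel receive
#' 0.6x intensity attenuation and 50% of the vessel's redraw
#' probability (shadowing and decorrelation leakage). Activation
#' pixels have mean intensity `Ib * (1 + template(t) * E)` where the
#' template scales linearly with radiant exposure `E`; per-trial
#' amplitudes carry multiplicative Gaussian jitter (CV from the
#' scene). Zero-mean Gaussian detector noise is added and intensities
#' are clipped at zero.
#'
#' @param protocol an [ins_protocol()].
#' @param scene an [ins_scene()].
#' @param exposure radiant exposure in J/cm^2.
#' @param seed integer seed; fixed-seed output is bit-reproducible.
#' @param fps OCT frame rate; defaults to `protocol$oct_fps`.
#' @param stim if `FALSE`, a blank (no stimulation) condition is
#'   generated: no activation modulation and no hemodynamic velocity
#'   response.
#' @return An object of class `bm_series`: list with `data` (list of
#'   3-D arrays, one per trial), `protocol`, `fps`, `exposure`,
#'   `modality = "oct"`, `trial_index`, and `ground_truth` (activation
#'   and vessel/tail masks, template parameters, per-trial amplitude
#'   jitters, seed).
#' @examples
#' p <- ins_protocol(poststim_s = 1, n_trials = 2, n_z = 24, n_x = 24)
#' s <- ins_scene(p)
#' bm <- simulate_bm_series(p, s, exposure = 1, seed = 1)
#' dim(bm$data[[1]])
#' @export
simulate_bm_series <- function(protocol, scene, exposure = 1.0, seed,
                               fps = protocol$oct_fps, stim = TRUE) {
  validate_protocol(protocol)
  stopifnot(inherits(scene, "ins_scene"))
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  set.seed(as.integer(seed))
  jit <- pmax(0.1, 1 + scene$trial_cv * stats::rnorm(protocol$n_trials))
  trials <- vector("list", protocol$n_trials)
  for (i in seq_len(protocol$n_trials))
    trials[[i]] <- sim_bm_trial(protocol, scene, exposure, fps,
                                amp_jitter = if (stim) jit[i] else 0,
                                stim = stim)
  mov <- scene_moving_pixels(scene)
  gt <- structure(list(activation = scene$activation,
                       vessel_mask = mov$vessel_mask,
                       tail_mask = mov$tail_mask,
                       vessels = scene$vessels,
                       template = scene$template,
                       hemo_onset_s = attr(scene$hemo, "onset_delay_s"),
                       amp_jitter = if (stim) jit else rep(0, protocol$n_trials),
                       exposure = exposure, fps = fps, seed = as.integer(seed),
                       stim = stim),
                  class = "ground_truth")
  structure(list(data = trials, protocol = protocol, fps = fps,
                 exposure = exposure, modality = "oct",
                 trial_index = seq_len(protocol$n_trials),
                 ground_truth = gt),
            class = "bm_series")
}

# one B-M trial; RNG state is taken as-is (caller seeds the stream)
sim_bm_trial <- function(protocol, scene, exposure, fps, amp_jitter,
                         stim = TRUE) {
  nz <- protocol$n_z; nx <- protocol$n_x
  nt <- as.integer(round(trial_duration(protocol) * fps))
  npx <- nz * nx
  tt <- (seq_len(nt) - 1) / fps - protocol$prestim_s
  dt <- 1 / fps

  R <- scene$reflectivity
  mov <- scene_moving_pixels(scene)
  R <- R * ifelse(mov$tail_mask, 0.6, 1)  # shadow attenuation

  S <- matrix(stats::rexp(npx), nz, nx)   # per-trial static speckle
  M <- matrix(as.vector(R * S), npx, nt)  # npx x nt working matrix

  if (length(mov$idx)) {
    h <- if (stim) scene$hemo(tt, exposure) else numeric(nt)
    base_m <- pmin(1, mov$velocity * 1e3 * dt / scene$beam_width_um) * mov$mixing
    nmv <- length(mov$idx)
    cur <- stats::rexp(nmv)
    Mm <- matrix(0, nmv, nt)
    for (k in seq_len(nt)) {
      mk <- pmin(1, base_m * (1 + h[k] * mov$hemo))
      rd <- stats::runif(nmv) < mk
      if (any(rd)) cur[rd] <- stats::rexp(sum(rd))
      Mm[, k] <- cur
    }
    M[mov$idx, ] <- as.vector(R)[mov$idx] * Mm
  }

  act <- which(scene$activation & !(mov$vessel_mask | mov$tail_mask))
  if (length(act) && stim && amp_jitter > 0) {
    tpl <- template_eval(scene$template, tt, exposure) * amp_jitter
    if (any(tpl != 0))
      M[act, ] <- M[act, , drop = FALSE] *
        rep(1 + tpl, each = length(act))
  }

  if (scene$noise_sd > 0)
    M <- M + stats::rnorm(npx * nt, sd = scene$noise_sd)
  M[M < 0] <- 0
  array(M, dim = c(nz, nx, nt))
}

#' Simulate an OISI frame series
#'
#' En-face (x-y) camera reflectance series: a static scene (uniform
#' tissue with dark surface vessels, shared with the OCT scene so the
#' two modalities can be coregistered) on which the activation disc
#' darkens following the OISI response template (`sign = -1`), plus
#' additive camera noise. Trial structure, jitter and exposure scaling
#' mirror [simulate_bm_series()].
#'
#' @inheritParams simulate_bm_series
#' @param fps OISI frame rate; defaults to `protocol$oisi_fps`.
#' @return A `bm_series` with `modality = "oisi"` and `(n_y, n_x,
#'   frames)` trial arrays.
#' @export
simulate_oisi_series <- function(protocol, scene, exposure = 1.0, seed,
                                 fps = protocol$oisi_fps, stim = TRUE) {
  validate_protocol(protocol)
  stopifnot(inherits(scene, "ins_scene"))
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  set.seed(as.integer(seed))
  nt <- as.integer(round(trial_duration(protocol) * fps))
  tt <- (seq_len(nt) - 1) / fps - protocol$prestim_s
  R <- scene$oisi_reflectance
  ny <- nrow(R); nx <- ncol(R); npx <- ny * nx
  act <- which(scene$oisi_activation)
  nsd <- scene$oisi_noise_sd * mean(R)

  jit <- pmax(0.1, 1 + scene$trial_cv * stats::rnorm(protocol$n_trials))
  trials <- vector("list", protocol$n_trials)
  for (i in seq_len(protocol$n_trials)) {
    M <- matrix(as.vector(R), npx, nt)
    if (length(act) && stim) {
      tpl <- template_eval(scene$oisi_template, tt, exposure) * jit[i]
      if (any(tpl != 0))
        M[act, ] <- M[act, , drop = FALSE] * rep(1 + tpl, each = length(act))
    }
    if (nsd > 0) M <- M + stats::rnorm(npx * nt, sd = nsd)
    M[M < 0] <- 0
    trials[[i]] <- array(M, dim = c(ny, nx, nt))
  }
  gt <- structure(list(activation = scene$oisi_activation,
                       template = scene$oisi_template,
                       amp_jitter = if (stim) jit else rep(0, protocol$n_trials),
                       exposure = exposure, fps = fps,
                       seed = as.integer(seed), stim = stim),
                  class = "ground_truth")
  structure(list(data = trials, protocol = protocol, fps = fps,
                 exposure = exposure, modality = "oisi",
                 trial_index = seq_len(protocol$n_trials),
                 ground_truth = gt),
            class = "bm_series")
}

#' Simulate flow-phantom B-M series at controlled velocities
#'
#' One single-trial series per requested velocity: a uniform
#' scattering phantom whose speckle is redrawn at a rate proportional
#' to the programmed velocity. `v = 0` yields a static series whose
#' interframe decorrelation reflects only the additive noise floor.
#'
#' @param velocities numeric vector of scatterer velocities in mm/s
#'   (all >= 0).
#' @param protocol an [ins_protocol()]; its frame rate, frame size and
#'   trial duration are used.
#' @param seed integer seed.
#' @param noise_sd additive noise SD (phantom reflectivity is 1).
#' @param beam_width_um lateral resolution for the mixing fraction.
#' @return A list of single-trial `bm_series`, one per velocity, each
#'   carrying its programmed velocity in `$velocity_mm_s`.
#' @export
simulate_flow_phantom <- function(velocities, protocol, seed,
                                  noise_sd = 0.05, beam_width_um = 10) {
  validate_protocol(protocol)
  if (any(velocities < 0)) stop("phantom velocities must be >= 0")
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  set.seed(as.integer(seed))
  nz <- protocol$n_z; nx <- protocol$n_x; npx <- nz * nx
  nt <- as.integer(round(trial_duration(protocol) * protocol$oct_fps))
  dt <- 1 / protocol$oct_fps
  out <- vector("list", length(velocities))
  for (j in seq_along(velocities)) {
    v <- velocities[j]
    m <- min(1, v * 1e3 * dt / beam_width_um)
    cur <- stats::rexp(npx)
    M <- matrix(0, npx, nt)
    for (k in seq_len(nt)) {
      if (m > 0) {
        rd <- stats::runif(npx) < m
        if (any(rd)) cur[rd] <- stats::rexp(sum(rd))
      }
      M[, k] <- cur
    }
    if (noise_sd > 0) M <- M + stats::rnorm(npx * nt, sd = noise_sd)
    M[M < 0] <- 0
    out[[j]] <- structure(list(data = list(array(M, dim = c(nz, nx, nt))),
                               protocol = protocol, fps = protocol$oct_fps,
                               exposure = 0, modality = "oct",
                               trial_index = 1L,
                               velocity_mm_s = v),
                          class = "bm_series")
  }
  out
}

#' Simulate stimulus-locked Poisson spike trains
#'
#' Inhomogeneous-Poisson spike timestamps per trial: the firing rate
#' steps from `baseline_rate_hz` to `stim_rate_hz` at INS onset plus
#' `onset_latency_s`, and back to baseline at INS offset. Timestamps
#' are INS-onset-locked seconds, sorted ascending.
#'
#' @param protocol an [ins_protocol()] (trial timing).
#' @param baseline_rate_hz spontaneous firing rate (Hz).
#' @param stim_rate_hz firing rate during the INS drive (Hz).
#' @param onset_latency_s spike-rate onset latency after INS onset;
#'   default 4 ms.
#' @param n_trials number of trials; the electrophysiology protocol
#'   default is 30.
#' @param seed integer seed.
#' @return An object of class `spike_data`: list with `trials` (list
#'   of numeric timestamp vectors), the protocol, rates, latency and
#'   seed.
#' @export
simulate_spike_trains <- function(protocol, baseline_rate_hz = 5,
                                  stim_rate_hz = 200,
                                  onset_latency_s = 0.004,
                                  n_trials = 30, seed) {
  validate_protocol(protocol)
  if (baseline_rate_hz < 0 || stim_rate_hz < 0) stop("rates must be >= 0")
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  set.seed(as.integer(seed))
  t0 <- -protocol$prestim_s
  t_end <- protocol$stim_s + protocol$poststim_s
  segs <- rbind(c(t0, onset_latency_s, baseline_rate_hz),
                c(onset_latency_s, protocol$stim_s, stim_rate_hz),
                c(protocol$stim_s, t_end, baseline_rate_hz))
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    ts <- numeric(0)
    for (r in seq_len(nrow(segs))) {
      a <- segs[r, 1]; b <- segs[r, 2]; rate <- segs[r, 3]
      if (b <= a || rate <= 0) next
      n <- stats::rpois(1, rate * (b - a))
      if (n > 0) ts <- c(ts, stats::runif(n, a, b))
    }
    trials[[i]] <- sort(ts)
  }
  structure(list(trials = trials, protocol = protocol,
                 baseline_rate_hz = baseline_rate_hz,
                 stim_rate_hz = stim_rate_hz,
                 onset_latency_s = onset_latency_s,
                 sampling_rate_hz = 30000, threshold_mv = -41,
                 seed = as.integer(seed)),
            class = "spike_data")
}

#' @export
print.bm_series <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("%s B-M series: %d trial(s) of %d x %d x %d at %g fps",
              toupper(x$modality), length(x$data), d[1], d[2], d[3], x$fps))
  if (!is.null(x$velocity_mm_s))
    cat(sprintf(" (phantom, v = %g mm/s)", x$velocity_mm_s))
  else cat(sprintf(", exposure %g J/cm2", x$exposure))
  cat("\n")
  invisible(x)
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("spike data: %d trial(s), %d spikes total\n",
              length(x$trials), sum(lengths(x$trials))))
  invisible(x)
}
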