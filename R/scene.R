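#' Synthetic cortical scene for the B-M-mode generator
#'
#' Describes the static cross-section that the synthetic B-M-mode
#' generator images: a per-pixel mean reflectivity map with exponential
#' depth attenuation, a spatially confined activation region whose
#' reflectivity is modulated by the stimulus-locked response template,
#' vessel regions containing moving scatterers (with per-vessel
#' velocity and an optional hemodynamic velocity response), and the
#' en-face (x-y) counterparts used by the OISI generator, including a
#' surface vessel pattern shared between modalities so coregistration
#' is testable.
#'
#' Defaults: the activation region is a disc of 0.4 mm lateral diameter
#' centered on the stimulation locus, extending from the surface to
#' 500 um depth; reflectivity decays with depth with a 300-um
#' attenuation length; one superficial pial vessel (1.0 mm/s) lies
#' outside the activation region and one capillary (0.3 mm/s) inside
#' it; additive detector noise has SD equal to 5% of the mean tissue
#' reflectivity; OISI additive noise is 0.2% of the mean reflectance
#' (a shot-noise-limited camera, low enough that the programmed OISI
#' latency is recoverable by the onset estimator);
#' trial-to-trial amplitude jitter is multiplicative Gaussian with
#' CV = 20%.
#'
#' @param protocol an [ins_protocol()]; fixes the frame geometry.
#' @param reflectivity optional `n_z x n_x` matrix of mean intensities
#'   (arbitrary units, >= 0).
#' @param activation optional logical `n_z x n_x` matrix marking the
#'   activated pixels.
#' @param vessels list of vessels, each a list with integer index
#'   vectors `z` and `x` (a rectangular block), `velocity_mm_s`, and
#'   logical `hemo` (does the vessel follow the hemodynamic velocity
#'   response). `NULL` gives the two default vessels; `list()` gives an
#'   avascular scene.
#' @param template the fOCT [response_template()].
#' @param oisi_tpl the OISI [response_template()] (darkening).
#' @param hemo the hemodynamic velocity profile, see [hemo_profile()].
#' @param noise_sd additive detector noise SD; default 5% of the mean
#'   reflectivity.
#' @param oisi_noise_sd additive OISI camera noise SD, as a fraction of
#'   mean reflectance.
#' @param trial_cv coefficient of variation of the multiplicative
#'   trial-to-trial amplitude jitter.
#' @param beam_width_um lateral resolution; sets the scatterer-refresh
#'   mixing fraction `min(1, v * dt / beam_width)`.
#' @param activation_diameter_mm,activation_depth_um default activation
#'   geometry.
#' @return An object of class `ins_scene`.
#' @export
ins_scene <- function(protocol,
                      reflectivity = NULL,
                      activation = NULL,
                      vessels = NULL,
                      template = response_template(),
                      oisi_tpl = oisi_template(),
                      hemo = hemo_profile(),
                      noise_sd = NULL,
                      oisi_noise_sd = 0.002,
                      trial_cv = 0.2,
                      beam_width_um = 10,
                      activation_diameter_mm = 0.4,
                      activation_depth_um = 500) {
  validate_protocol(protocol)
  nz <- protocol$n_z; nx <- protocol$n_x
  z_um <- (seq_len(nz) - 1) * protocol$z_pitch_um

  if (is.null(reflectivity))
    reflectivity <- matrix(exp(-z_um / 300), nz, nx)
  if (!all(dim(reflectivity) == c(nz, nx)))
    stop("reflectivity map must be ", nz, " x ", nx)
  if (any(!is.finite(reflectivity)) || any(reflectivity < 0))
    stop("reflectivity must be finite and >= 0")
  if (all(reflectivity == 0)) stop("empty scene: reflectivity is all zero")

  if (is.null(activation)) {
    cx <- (nx + 1) / 2
    rad_px <- activation_diameter_mm * 1e3 / 2 / protocol$x_pitch_um
    lat <- abs(col(reflectivity) - cx) <= rad_px
    dep <- matrix(z_um < activation_depth_um, nz, nx)
    activation <- lat & dep
  }
  if (!is.logical(activation) || !all(dim(activation) == c(nz, nx)))
    stop("activation must be a logical ", nz, " x ", nx, " matrix")

  if (is.null(vessels)) {
    vessels <- list(
      list(z = 3:6,   x = 4:9,   velocity_mm_s = 1.0, hemo = TRUE),
      list(z = 21:23, x = 31:33, velocity_mm_s = 0.3, hemo = TRUE))
    vessels <- Filter(function(v) max(v$z) <= nz && max(v$x) <= nx, vessels)
  }
  for (v in vessels) {
    if (min(v$z) < 1 || max(v$z) > nz || min(v$x) < 1 || max(v$x) > nx)
      stop("vessel region outside the frame")
    if (v$velocity_mm_s < 0) stop("vessel velocity must be >= 0")
  }

  if (is.null(noise_sd)) noise_sd <- 0.05 * mean(reflectivity)

  # en-face (x-y) scene for OISI: uniform reflectance with dark surface
  # vessels and a central activation disc of the same diameter
  ny <- nx
  refl2 <- matrix(1, ny, nx)
  sv <- matrix(FALSE, ny, nx)
  yb <- intersect(seq_len(ny), round(ny * 0.25) + 0:2)
  xb <- intersect(seq_len(nx), round(nx * 0.65) + 0:2)
  sv[yb, ] <- TRUE
  sv[, xb] <- TRUE
  dg <- which(abs(row(refl2) - col(refl2) - round(ny * 0.15)) <= 1)
  sv[dg] <- TRUE
  refl2[sv] <- 0.55
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  rad_px <- activation_diameter_mm * 1e3 / 2 / protocol$x_pitch_um
  act2 <- (row(refl2) - cy)^2 + (col(refl2) - cx)^2 <= rad_px^2

  s <- list(protocol = protocol, reflectivity = reflectivity,
            activation = activation, vessels = vessels,
            template = template, oisi_template = oisi_tpl, hemo = hemo,
            noise_sd = noise_sd, oisi_noise_sd = oisi_noise_sd,
            trial_cv = trial_cv, beam_width_um = beam_width_um,
            oisi_reflectance = refl2, oisi_activation = act2,
            surface_vessels = sv)
  class(s) <- "ins_scene"
  s
}

#' Single-vessel scene for velocity-index experiments
#'
#' A convenience scene containing one superficial vessel block and no
#' programmed scattering activation, used to study the blood-flow
#' velocity index (ROI-mean interframe decorrelation) and its
#' hemodynamic onset. The default vessel is a small pial arteriole
#' (0.8 mm/s): fast enough that the 50% hyperemic velocity step
#' raises the decorrelation index several baseline SDs above the
#' onset threshold, so the programmed 1-s latency is recoverable at
#' frame-pair precision.
#'
#' @inheritParams ins_scene
#' @param velocity_mm_s baseline scatterer velocity of the vessel.
#' @param z,x index ranges of the vessel block.
#' @return An `ins_scene` whose only dynamic structure is the vessel.
#' @export
vessel_scene <- function(protocol, velocity_mm_s = 0.8,
                         z = 5:14, x = 28:37, ...) {
  ins_scene(protocol,
            activation = matrix(FALSE, protocol$n_z, protocol$n_x),
            vessels = list(list(z = z, x = x,
                                velocity_mm_s = velocity_mm_s, hemo = TRUE)),
            ...)
}

#' @export
print.ins_scene <- function(x, ...) {
  cat("synthetic INS-fOCT scene\n")
  cat(sprintf("  frame %d x %d px; activation %d px; %d vessel(s); noise SD %.4g\n",
              nrow(x$reflectivity), ncol(x$reflectivity),
              sum(x$activation), length(x$vessels), x$noise_sd))
  invisible(x)
}

# vessel pixel bookkeeping: linear indices of vessel pixels, their
# velocities and hemo flags, plus tail-artifact pixels (the rest of
# each A-line below a vessel pixel) with 50% of the vessel's mixing
# and a 0.6 intensity attenuation.
scene_moving_pixels <- function(scene) {
  nz <- nrow(scene$reflectivity); nx <- ncol(scene$reflectivity)
  idx <- integer(0); vel <- numeric(0); hemo <- logical(0)
  mixf <- numeric(0); atten <- numeric(0)
  vessel_mask <- matrix(FALSE, nz, nx)
  tail_mask <- matrix(FALSE, nz, nx)
  for (v in scene$vessels) {
    m <- matrix(FALSE, nz, nx); m[v$z, v$x] <- TRUE
    vessel_mask <- vessel_mask | m
    i <- which(m)
    idx <- c(idx, i)
    vel <- c(vel, rep(v$velocity_mm_s, length(i)))
    hemo <- c(hemo, rep(isTRUE(v$hemo), length(i)))
    mixf <- c(mixf, rep(1, length(i)))
    atten <- c(atten, rep(1, length(i)))
    # tail artifact: below the vessel to the bottom of each A-line
    tm <- matrix(FALSE, nz, nx)
    zb <- max(v$z)
    if (zb < nz) tm[(zb + 1):nz, v$x] <- TRUE
    tm <- tm & !vessel_mask
    ti <- which(tm & !tail_mask)
    tail_mask <- tail_mask | tm
    idx <- c(idx, ti)
    vel <- c(vel, rep(v$velocity_mm_s, length(ti)))
    hemo <- c(hemo, rep(isTRUE(v$hemo), length(ti)))
    mixf <- c(mixf, rep(0.5, length(ti)))
    atten <- c(atten, rep(0.6, length(ti)))
  }
  keep <- !duplicated(idx)
  list(idx = idx[keep], velocity = vel[keep], hemo = hemo[keep],
       mixing = mixf[keep], atten = atten[keep],
       vessel_mask = vessel_mask, tail_mask = tail_mask)
}
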