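#' Instrument model for the simulated SFDI system
#'
#' Describes the virtual structured-illumination imager: LED wavelengths,
#' projected spatial frequencies and phase offsets, image grid, per-pixel
#' illumination gain, system modulation transfer factor, additive noise,
#' session gain drift, and the height-dependent intensity model the
#' preprocessing inverts.
#'
#' The default grid is 64 x 64 pixels at 0.5 mm pitch (a 32 x 32 mm field),
#' a desk-scale reduction of the instrument's 150 x 200 mm field of view.
#'
#' @param n_px image grid size (pixels per side)
#' @param pixel_pitch_mm pixel pitch, mm
#' @param wavelengths LED wavelengths, nm
#' @param fx projected spatial frequencies, mm^-1 (must contain 0)
#' @param phases phase offsets in degrees (exactly 3, equally spaced)
#' @param mtf_ac system modulation transfer factor at the AC frequency, in (0, 1]
#' @param noise_frac additive Gaussian noise sigma as a fraction of the local
#'   DC signal
#' @param drift_sd log-sd of the per-acquisition multiplicative session gain
#'   drift relative to the day's calibration measurement
#' @param height_gain_per_mm linear intensity gain per mm of surface
#'   elevation (the generative height model; preprocessing divides it out)
#' @param n_rel relative refractive index assumed for the tissue
#' @param gain_map optional n_px x n_px relative illumination map; defaults
#'   to a mild radial vignette
#' @return list of class `sfdi_instrument`
#' @export
instrument_model <- function(n_px = 64, pixel_pitch_mm = 0.5,
                             wavelengths = c(659, 691, 731, 851),
                             fx = c(0, 0.1), phases = c(0, 120, 240),
                             mtf_ac = 0.7, noise_frac = 0.01,
                             drift_sd = 0.02, height_gain_per_mm = -0.02,
                             n_rel = 1.4, gain_map = NULL) {
  if (length(phases) != 3 || !isTRUE(all.equal(diff(sort(phases)), c(120, 120)))) {
    stop("exactly 3 equally spaced (120 degree) phases are required")
  }
  if (!0 %in% fx) stop("spatial frequency list must contain 0")
  if (length(fx) != 2 || any(fx < 0)) stop("exactly two frequencies (0 and one AC) supported")
  if (mtf_ac <= 0 || mtf_ac > 1) stop("mtf must be in (0, 1]")
  if (is.null(gain_map)) {
    half <- (n_px - 1) / 2
    r2 <- outer((seq_len(n_px) - 1 - half)^2, (seq_len(n_px) - 1 - half)^2, "+")
    gain_map <- 1 - 0.2 * r2 / max(r2)
  }
  stopifnot(all(dim(gain_map) == c(n_px, n_px)), all(gain_map > 0))
  structure(list(
    n_px = n_px, pixel_pitch_mm = pixel_pitch_mm,
    fov_mm = n_px * pixel_pitch_mm,
    wavelengths = wavelengths, fx = sort(fx), phases = phases,
    mtf_ac = mtf_ac, noise_frac = noise_frac, drift_sd = drift_sd,
    height_gain_per_mm = height_gain_per_mm, n_rel = n_rel,
    gain_map = gain_map
  ), class = "sfdi_instrument")
}

.empty_scene <- function(n_px, wavelengths) {
  z <- matrix(0, n_px, n_px)
  structure(list(
    n_px = n_px, wavelengths = wavelengths,
    mua = array(NA_real_, c(n_px, n_px, length(wavelengths))),
    musp = array(NA_real_, c(n_px, n_px, length(wavelengths))),
    height_mm = z, angle_deg = z,
    tumor_mask = matrix(FALSE, n_px, n_px),
    inframe_mask = matrix(FALSE, n_px, n_px)
  ), class = "sfdi_scene")
}

#' Homogeneous flat phantom scene
#'
#' A spatially homogeneous, flat (height 0, angle 0) scene carrying the
#' given optical properties at each instrument wavelength, standing in for
#' a tissue-mimicking calibration phantom.
#'
#' @param props data.frame with columns `wavelength`, `mua`, `musp` covering
#'   every instrument wavelength
#' @param instrument an [instrument_model()]
#' @return list of class `sfdi_scene`
#' @export
make_phantom_scene <- function(props, instrument) {
  stopifnot(is.data.frame(props), all(c("wavelength", "mua", "musp") %in% names(props)))
  if (any(props$mua <= 0) || any(props$musp <= 0)) stop("phantom properties must be positive")
  sc <- .empty_scene(instrument$n_px, instrument$wavelengths)
  for (k in seq_along(instrument$wavelengths)) {
    i <- match(instrument$wavelengths[k], props$wavelength)
    if (is.na(i)) stop("phantom properties missing wavelength ", instrument$wavelengths[k])
    sc$mua[, , k] <- props$mua[i]
    sc$musp[, , k] <- props$musp[i]
  }
  sc
}

#' Tumor scene: spherical-cap bump on a flat tissue background
#'
#' Builds the per-wavelength optical-property maps for one subject on one
#' measurement day. The tumor is modeled as a hemispherical cap whose
#' footprint radius follows volume^(1/3) scaling
#' (\eqn{V = \tfrac{2}{3}\pi r^3}); inside the footprint the reduced
#' scattering follows the subject's power-law parameters (a, b) and the
#' absorption follows Beer's law from (ctHbO2, ctHHb). The background
#' carries configured normal-tissue biomarkers, and an in-frame reference
#' phantom patch (for session drift correction) sits in a corner outside
#' the animal footprint. The surface height and normal-angle maps are the
#' exact cap geometry: height \eqn{h = \sqrt{r^2 - d^2}}, angle
#' \eqn{\theta = \arccos(h / r)}.
#'
#' @param biomarkers list with `a`, `b` (scattering power law, mm^-1 and
#'   dimensionless) and `ctHbO2`, `ctHHb` (uM)
#' @param volume_mm3 tumor volume, mm^3 (> 0)
#' @param background normal-tissue biomarkers, same components as `biomarkers`
#' @param phantom_props data.frame (`wavelength`, `mua`, `musp`) for the
#'   in-frame phantom patch
#' @param instrument an [instrument_model()]
#' @param ext extinction table
#' @return list of class `sfdi_scene`
#' @export
make_tumor_scene <- function(biomarkers, volume_mm3, background, phantom_props,
                             instrument, ext) {
  if (volume_mm3 < 0) stop("volume must be non-negative")
  n <- instrument$n_px
  pitch <- instrument$pixel_pitch_mm
  wl <- instrument$wavelengths
  sc <- .empty_scene(n, wl)

  bg_musp <- scatter_power_law(background$a, background$b, wl)
  bg_mua <- mua_from_chromophores(background$ctHbO2, background$ctHHb, wl, ext)
  tu_musp <- scatter_power_law(biomarkers$a, biomarkers$b, wl)
  tu_mua <- mua_from_chromophores(biomarkers$ctHbO2, biomarkers$ctHHb, wl, ext)
  if (any(tu_mua <= 0) || any(bg_mua <= 0)) {
    stop("tissue absorption must be positive (nonzero hemoglobin required)")
  }

  ## hemispherical cap: V = (2/3) pi r^3
  r_mm <- (3 * volume_mm3 / (2 * pi))^(1 / 3)
  cx <- (n + 1) / 2  # center, pixel units
  ## in-frame phantom patch: pixels 2..7 in each dimension (corner)
  patch <- 2:7
  patch_far_mm <- max(patch) * pitch
  ctr_mm <- cx * pitch
  if (r_mm > instrument$fov_mm / 2 - 2 ||
      r_mm > sqrt(2) * (ctr_mm - patch_far_mm) - 1) {
    stop("tumor footprint exceeds usable field of view")
  }

  px <- seq_len(n)
  d_mm <- sqrt(outer((px - cx)^2, (px - cx)^2, "+")) * pitch
  in_cap <- d_mm < r_mm

  for (k in seq_along(wl)) {
    mua_k <- matrix(bg_mua[k], n, n)
    musp_k <- matrix(bg_musp[k], n, n)
    mua_k[in_cap] <- tu_mua[k]
    musp_k[in_cap] <- tu_musp[k]
    i <- match(wl[k], phantom_props$wavelength)
    mua_k[patch, patch] <- phantom_props$mua[i]
    musp_k[patch, patch] <- phantom_props$musp[i]
    sc$mua[, , k] <- mua_k
    sc$musp[, , k] <- musp_k
  }
  h <- matrix(0, n, n)
  h[in_cap] <- sqrt(pmax(0, r_mm^2 - d_mm[in_cap]^2))
  ang <- matrix(0, n, n)
  ang[in_cap] <- acos(pmin(1, h[in_cap] / r_mm)) * 180 / pi
  sc$height_mm <- h
  sc$angle_deg <- ang
  sc$tumor_mask <- in_cap
  sc$inframe_mask[patch, patch] <- TRUE
  sc
}

#' Simulate a raw phase-shifted SFDI image stack
#'
#' Generates one frame per (wavelength, spatial frequency, phase). Each
#' frame is
#' \deqn{I(x) = g\, gain(x)\, hf(x)\, \cos\theta(x)\, [R_d(0)/2 +
#'   mtf\, R_d(f_x)/2 \cos(2\pi f_x x + \phi)] + \epsilon}
#' for the AC frequency, and \eqn{I(x) = g\, gain(x)\, hf(x) \cos\theta(x)
#' R_d(0) + \epsilon} for the planar (fx = 0) frames, which carry no
#' sinusoidal term. `hf` is the linear height intensity factor
#' \eqn{1 + k_h\, h(x)}, `g` the per-acquisition session drift gain, and
#' \eqn{\epsilon} zero-mean Gaussian noise with sigma equal to
#' `noise_frac` times the local DC signal. Negative intensities are clipped
#' to zero.
#'
#' @param scene an `sfdi_scene`
#' @param instrument an [instrument_model()]
#' @param seed optional integer; when given, the noise stream is seeded
#'   locally so identical calls are bit-identical
#' @param drift_gain multiplicative session drift for this acquisition
#' @param meta optional list stored alongside the frames
#' @return list of class `sfdi_raw` with a 5-D `frames` array indexed
#'   `[x, y, wavelength, fx, phase]`
#' @export
simulate_raw_images <- function(scene, instrument, seed = NULL,
                                drift_gain = 1, meta = list()) {
  stopifnot(inherits(scene, "sfdi_scene"), inherits(instrument, "sfdi_instrument"))
  if (scene$n_px != instrument$n_px) stop("scene and instrument grids differ")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- instrument$n_px
  wl <- instrument$wavelengths
  fxs <- instrument$fx
  fac <- fxs[fxs > 0]
  phases_rad <- instrument$phases * pi / 180
  x_mm <- matrix(rep((seq_len(n) - 1) * instrument$pixel_pitch_mm, each = n), n, n)
  cos_ang <- cos(scene$angle_deg * pi / 180)
  hf <- 1 + instrument$height_gain_per_mm * scene$height_mm
  envelope <- drift_gain * instrument$gain_map * hf * cos_ang

  frames <- array(NA_real_, c(n, n, length(wl), length(fxs), 3))
  for (k in seq_along(wl)) {
    rd0 <- .rd_diffusion(scene$mua[, , k], scene$musp[, , k], 0, instrument$n_rel)
    rd1 <- .rd_diffusion(scene$mua[, , k], scene$musp[, , k], fac, instrument$n_rel)
    dc_local <- envelope * rd0
    sigma <- instrument$noise_frac * dc_local
    for (p in 1:3) {
      i0 <- match(0, fxs)
      frames[, , k, i0, p] <- pmax(0, dc_local + stats::rnorm(n * n) * sigma)
      i1 <- match(fac, fxs)
      modterm <- rd0 / 2 + instrument$mtf_ac * rd1 / 2 *
        cos(2 * pi * fac * x_mm + phases_rad[p])
      frames[, , k, i1, p] <- pmax(0, envelope * modterm + stats::rnorm(n * n) * sigma)
    }
  }
  structure(list(frames = frames, wavelengths = wl, fx = fxs,
                 phases = instrument$phases,
                 pixel_pitch_mm = instrument$pixel_pitch_mm,
                 meta = c(meta, list(seed = seed, drift_gain = drift_gain))),
            class = "sfdi_raw")
}
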