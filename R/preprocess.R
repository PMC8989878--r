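#' Three-phase demodulation of a raw SFDI stack
#'
#' Recovers the modulation amplitude envelope from the three phase-shifted
#' frames at each (wavelength, frequency):
#' \deqn{M_{AC} = \frac{\sqrt{2}}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2}}
#' \deqn{M_{DC} = (I_1 + I_2 + I_3) / 3}
#' These identities are exact for any pure three-phase sinusoid
#' \eqn{I_i = A + B\cos(\phi_0 + \theta_i)} with 120-degree phase spacing:
#' they return \eqn{M_{AC} = B} and \eqn{M_{DC} = A} pointwise. The planar
#' (fx = 0) triple yields the DC amplitude.
#'
#' @param raw an `sfdi_raw` stack
#' @return list of class `sfdi_demod` with `m_dc` and `m_ac` arrays
#'   `[x, y, wavelength]`
#' @export
demodulate <- function(raw) {
  stopifnot(inherits(raw, "sfdi_raw"))
  fr <- raw$frames
  if (length(dim(fr)) != 5 || dim(fr)[5] != 3) stop("expected 3 phase frames per (wavelength, fx)")
  if (any(!is.finite(fr))) stop("raw frames contain non-finite intensities")
  n_wl <- dim(fr)[3]
  i0 <- match(0, raw$fx)
  iac <- which(raw$fx > 0)
  if (is.na(i0) || length(iac) != 1) stop("need fx = 0 and exactly one AC frequency")
  n <- dim(fr)[1]
  m_dc <- array(NA_real_, c(n, n, n_wl))
  m_ac <- array(NA_real_, c(n, n, n_wl))
  for (k in seq_len(n_wl)) {
    m_dc[, , k] <- (fr[, , k, i0, 1] + fr[, , k, i0, 2] + fr[, , k, i0, 3]) / 3
    I1 <- fr[, , k, iac, 1]; I2 <- fr[, , k, iac, 2]; I3 <- fr[, , k, iac, 3]
    m_ac[, , k] <- sqrt(2) / 3 * sqrt((I1 - I2)^2 + (I2 - I3)^2 + (I3 - I1)^2)
  }
  structure(list(m_dc = m_dc, m_ac = m_ac, wavelengths = raw$wavelengths,
                 fx = raw$fx, fx_ac = raw$fx[iac], n_px = n),
            class = "sfdi_demod")
}

## Clipped box-blur via integral images (edges renormalized by the actual
## window size). Used to denoise calibration-phantom maps.
.box_blur <- function(m, h) {
  n <- nrow(m); p <- ncol(m)
  ii <- rbind(0, apply(m, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  cnt_r <- pmin(seq_len(n) + h, n) - pmax(seq_len(n) - h, 1) + 1
  cnt_c <- pmin(seq_len(p) + h, p) - pmax(seq_len(p) - h, 1) + 1
  lo_r <- pmax(seq_len(n) - h, 1); hi_r <- pmin(seq_len(n) + h, n)
  lo_c <- pmax(seq_len(p) - h, 1); hi_c <- pmin(seq_len(p) + h, p)
  out <- (ii[hi_r + 1, hi_c + 1, drop = FALSE] -
          ii[lo_r, hi_c + 1, drop = FALSE] -
          ii[hi_r + 1, lo_c, drop = FALSE] +
          ii[lo_r, lo_c, drop = FALSE])
  out / outer(cnt_r, cnt_c)
}

#' Denoise a demodulated calibration measurement
#'
#' The calibration phantom is spatially homogeneous, so each demodulated
#' amplitude map is (spatial illumination profile) x (per-channel scalar)
#' plus acquisition noise; single-acquisition noise left in these maps
#' becomes a shared error in every measurement calibrated against them.
#' With `pool_gain = TRUE` (default) the shared illumination profile is
#' estimated by averaging the normalized planar (fx = 0) maps -- by far
#' the least noisy channels -- lightly blurred, and every channel is
#' rebuilt as its own mean amplitude times that profile. This assumes the
#' spatial response is common across wavelengths and frequency channels
#' (true of a projector gain profile); set `pool_gain = FALSE` to fall
#' back to plain per-channel box-blurring.
#'
#' @param demod an `sfdi_demod` of a homogeneous phantom
#' @param half_width blur half-width in pixels (window `2h+1`; 0 disables
#'   all denoising)
#' @param pool_gain rebuild channels from the pooled planar-channel
#'   illumination profile (see Details)
#' @return denoised `sfdi_demod`
#' @export
smooth_calibration <- function(demod, half_width = 2, pool_gain = TRUE) {
  stopifnot(inherits(demod, "sfdi_demod"))
  if (half_width <= 0) return(demod)
  n_wl <- length(demod$wavelengths)
  if (pool_gain) {
    G <- 0
    for (k in seq_len(n_wl)) {
      G <- G + demod$m_dc[, , k] / mean(demod$m_dc[, , k])
    }
    G <- .box_blur(G / n_wl, half_width)
    for (k in seq_len(n_wl)) {
      demod$m_dc[, , k] <- mean(demod$m_dc[, , k] / G) * G
      demod$m_ac[, , k] <- mean(demod$m_ac[, , k] / G) * G
    }
  } else {
    for (k in seq_len(n_wl)) {
      demod$m_dc[, , k] <- .box_blur(demod$m_dc[, , k], half_width)
      demod$m_ac[, , k] <- .box_blur(demod$m_ac[, , k], half_width)
    }
  }
  demod
}

#' Calibrate demodulated amplitudes into diffuse reflectance maps
#'
#' Removes the system response (illumination gain, modulation transfer,
#' camera scaling) by ratioing against a measurement of a reference phantom
#' with known optical properties:
#' \deqn{R_d^{sample}(\lambda, f_x) = \frac{M^{sample}}{M^{reference}}
#'   R_d^{model}(\mu_a^{ref}, \mu_s'^{ref}, f_x)}
#' with the model reflectance from [sfd_reflectance()]. Pixels where the
#' reference amplitude is non-positive are masked invalid.
#'
#' @param sample `sfdi_demod` of the measured scene
#' @param reference `sfdi_demod` of the calibration phantom (same instrument
#'   geometry)
#' @param reference_props data.frame (`wavelength`, `mua`, `musp`) of the
#'   phantom's known properties
#' @param n_rel relative refractive index used in the reflectance model
#' @return list of class `sfdi_rd`: array `rd[x, y, wavelength, fx]` plus a
#'   per-pixel validity mask
#' @export
calibrate <- function(sample, reference, reference_props, n_rel = 1.4) {
  stopifnot(inherits(sample, "sfdi_demod"), inherits(reference, "sfdi_demod"))
  if (sample$n_px != reference$n_px) stop("sample and reference geometry differ")
  wl <- sample$wavelengths
  n <- sample$n_px
  rd <- array(NA_real_, c(n, n, length(wl), 2))
  valid <- matrix(TRUE, n, n)
  for (k in seq_along(wl)) {
    i <- match(wl[k], reference_props$wavelength)
    if (is.na(i)) stop("reference properties missing wavelength ", wl[k])
    rd_ref0 <- .rd_diffusion(reference_props$mua[i], reference_props$musp[i],
                             0, n_rel)
    rd_ref1 <- .rd_diffusion(reference_props$mua[i], reference_props$musp[i],
                             sample$fx_ac, n_rel)
    ok <- reference$m_dc[, , k] > 0 & reference$m_ac[, , k] > 0
    valid <- valid & ok
    rd[, , k, 1] <- ifelse(ok, sample$m_dc[, , k] / reference$m_dc[, , k] * rd_ref0, NA)
    rd[, , k, 2] <- ifelse(ok, sample$m_ac[, , k] / reference$m_ac[, , k] * rd_ref1, NA)
  }
  structure(list(rd = rd, wavelengths = wl, fx = c(0, sample$fx_ac),
                 valid = valid, n_px = n),
            class = "sfdi_rd")
}

#' In-frame phantom drift correction
#'
#' Corrects session-level multiplicative gain drift (lamp/camera changes
#' over a measurement day spanning hours) using a reference phantom kept in
#' the field of view. Each (wavelength, fx) map is multiplied by
#' (session-reference in-frame mean) / (current in-frame mean), so after
#' correction the in-frame mean equals the session reference exactly. The
#' correction is a uniform scale: pixel ratios are unchanged and invalid
#' pixels stay invalid.
#'
#' @param rd an `sfdi_rd`
#' @param inframe_mask logical matrix marking the in-frame phantom pixels
#' @param session_reference_rd matrix `[wavelength, fx]` of reference
#'   in-frame Rd values (the in-frame phantom's appearance at the session's
#'   calibration-time gain)
#' @param per_channel when `FALSE` (default) the drift factor is estimated
#'   per wavelength from the planar (fx = 0) channel and applied to both
#'   frequency channels: session drift is an illumination/camera gain,
#'   identical for the DC and AC channels of a wavelength, and the planar
#'   in-frame mean is by far the less noisy estimate of it. With `TRUE`
#'   each (wavelength, fx) map gets its own in-frame factor.
#' @return corrected `sfdi_rd`; attribute `drift_factors` records the
#'   applied factors, `drift_skipped` flags an empty mask
#' @export
drift_correct <- function(rd, inframe_mask, session_reference_rd,
                          per_channel = FALSE) {
  stopifnot(inherits(rd, "sfdi_rd"))
  if (!any(inframe_mask)) {
    warning("empty in-frame mask: drift correction skipped")
    attr(rd, "drift_skipped") <- TRUE
    return(rd)
  }
  n_wl <- length(rd$wavelengths)
  factors <- matrix(NA_real_, n_wl, 2)
  for (k in seq_len(n_wl)) {
    for (j in 1:2) {
      cur <- mean(rd$rd[, , k, j][inframe_mask & rd$valid])
      factors[k, j] <- session_reference_rd[k, j] / cur
    }
    if (!per_channel) factors[k, 2] <- factors[k, 1]
    for (j in 1:2) rd$rd[, , k, j] <- rd$rd[, , k, j] * factors[k, j]
  }
  attr(rd, "drift_factors") <- factors
  attr(rd, "drift_skipped") <- FALSE
  rd
}

#' Surface height and angle correction
#'
#' Inverts the generative surface-intensity model: divides each map by the
#' Lambertian angle factor \eqn{\cos\theta} and by the linear height gain
#' \eqn{1 + k_h h}. Pixels whose surface normal exceeds the 40-degree
#' threshold are set invalid after correction (the angle correction is not
#' trusted beyond that angle); corrections never resurrect already-invalid
#' pixels.
#'
#' @param rd an `sfdi_rd`
#' @param height_map surface height above the reference plane, mm
#' @param angle_deg_map surface normal angle from vertical, degrees
#' @param height_gain_per_mm the instrument's linear height gain coefficient
#' @param max_angle_deg mask threshold, degrees (default 40)
#' @return corrected `sfdi_rd` with updated validity mask
#' @export
surface_correct <- function(rd, height_map, angle_deg_map,
                            height_gain_per_mm, max_angle_deg = 40) {
  stopifnot(inherits(rd, "sfdi_rd"))
  if (!all(dim(height_map) == c(rd$n_px, rd$n_px)) ||
      !all(dim(angle_deg_map) == c(rd$n_px, rd$n_px))) {
    stop("surface maps not co-registered with reflectance maps")
  }
  corr <- cos(angle_deg_map * pi / 180) * (1 + height_gain_per_mm * height_map)
  ok <- angle_deg_map <= max_angle_deg & corr > 0
  for (k in seq_along(rd$wavelengths)) {
    for (j in 1:2) rd$rd[, , k, j] <- rd$rd[, , k, j] / corr
  }
  rd$valid <- rd$valid & ok
  rd
}
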