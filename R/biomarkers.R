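#' Per-pixel spectral fitting of biomarker maps
#'
#' Converts inverted per-wavelength optical-property maps into biomarker
#' maps: the scattering power law (amplitude `a` at 800 nm and power `b`)
#' is fit to the reduced-scattering spectrum, and hemoglobin concentrations
#' (ctHbO2, ctHHb, in uM) are fit to the absorption spectrum by
#' non-negative least squares against the extinction table. Composites
#' ctTHb = ctHbO2 + ctHHb and StO2 = ctHbO2 / ctTHb are computed per pixel.
#' Fits are pixel-independent (no spatial coupling or smoothing); a pixel
#' is valid only where every instrument wavelength inverted validly, and
#' invalid pixels propagate as NA.
#'
#' @param props an `sfdi_props` from [invert_maps()]
#' @param ext extinction table
#' @return list of class `sfdi_biomarkers`: matrices `a`, `b`, `ctHbO2`,
#'   `ctHHb`, `ctTHb`, `StO2`, a logical `valid` mask and an
#'   `sto2_defined` mask
#' @export
fit_biomarker_maps <- function(props, ext) {
  stopifnot(inherits(props, "sfdi_props"))
  n <- props$n_px
  wl <- props$wavelengths
  if (length(wl) < 2) stop("need at least 2 wavelengths for spectral fits")
  valid <- apply(props$valid, c(1, 2), all)
  idx <- which(valid)
  blank <- matrix(NA_real_, n, n)
  out <- list(a = blank, b = blank, ctHbO2 = blank, ctHHb = blank,
              ctTHb = blank, StO2 = blank, valid = valid,
              sto2_defined = matrix(FALSE, n, n))
  if (length(idx)) {
    MS <- sapply(seq_along(wl), function(k) props$musp[, , k][idx])
    MA <- sapply(seq_along(wl), function(k) props$mua[, , k][idx])
    MS <- matrix(MS, nrow = length(idx))
    MA <- matrix(MA, nrow = length(idx))
    pl <- .fit_power_law_mat(wl, MS)
    ch <- .fit_chromophores_mat(wl, MA, ext)
    out$a[idx] <- pl$a
    out$b[idx] <- pl$b
    out$ctHbO2[idx] <- ch$ctHbO2
    out$ctHHb[idx] <- ch$ctHHb
    out$ctTHb[idx] <- ch$ctTHb
    out$StO2[idx] <- ch$StO2
    out$sto2_defined[idx] <- ch$sto2_defined
  }
  out$n_px <- n
  class(out) <- "sfdi_biomarkers"
  out
}
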