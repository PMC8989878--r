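#' Diffuse reflectance of a semi-infinite homogeneous medium under
#' spatially modulated illumination
#'
#' Standard diffusion-approximation solution for the steady-state diffuse
#' reflectance of a semi-infinite turbid medium illuminated by a sinusoidal
#' pattern of spatial frequency `fx`. At a given frequency the medium responds
#' with a scalar attenuation governed by the effective transport coefficient
#' \eqn{\mu_{eff}'(f_x) = \sqrt{3 \mu_a \mu_{tr} + (2\pi f_x)^2}}, and the
#' remitted modulation amplitude is
#' \deqn{R_d(f_x) = \frac{3 A a'}{(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)}}
#' with reduced albedo \eqn{a' = \mu_s'/\mu_{tr}},
#' \eqn{\mu_{tr} = \mu_a + \mu_s'}, and the internal-reflection parameter
#' \eqn{A = (1 - R_{eff}) / (2 (1 + R_{eff}))} obtained from the effective
#' reflection coefficient of the refractive-index mismatch,
#' \eqn{R_{eff} \approx 0.0636 n + 0.668 + 0.710/n - 1.440/n^2}.
#'
#' `Rd` is strictly decreasing in both `fx` and `mua`, and tends to 1 as
#' \eqn{\mu_a \to 0} at \eqn{f_x = 0} (a lossless half-space returns all
#' light).
#'
#' @param mua absorption coefficient, mm^-1 (vectorized)
#' @param musp reduced scattering coefficient, mm^-1 (vectorized)
#' @param fx spatial frequency, mm^-1 (>= 0)
#' @param n_rel relative refractive index of the medium against the outside
#'   (default 1.4, typical tissue/air)
#' @return dimensionless diffuse reflectance in (0, 1)
#' @export
sfd_reflectance <- function(mua, musp, fx = 0, n_rel = 1.4) {
  if (any(!is.finite(mua)) || any(!is.finite(musp)) ||
      any(mua <= 0) || any(musp <= 0)) {
    stop("optical properties must be finite and positive", call. = FALSE)
  }
  if (any(!is.finite(fx)) || any(fx < 0)) {
    stop("spatial frequency must be finite and >= 0", call. = FALSE)
  }
  if (any(musp / mua < 10)) {
    warning("musp/mua ratio below 10: diffusion approximation may be inaccurate",
            call. = FALSE)
  }
  .rd_diffusion(mua, musp, fx, n_rel)
}

## Internal unchecked kernel; used in performance-critical loops (inversion)
## where inputs are already validated.
.rd_diffusion <- function(mua, musp, fx, n_rel) {
  reff <- 0.0636 * n_rel + 0.668 + 0.710 / n_rel - 1.440 / n_rel^2
  A <- (1 - reff) / (2 * (1 + reff))
  mutr <- mua + musp
  ap <- musp / mutr
  mueff_p <- sqrt(3 * mua * mutr + (2 * pi * fx)^2)
  x <- mueff_p / mutr
  3 * A * ap / ((x + 1) * (x + 3 * A))
}

#' Scattering power law
#'
#' Reduced scattering as a function of wavelength,
#' \eqn{\mu_s'(\lambda) = a (\lambda / 800)^{-b}}, where `a` is the
#' scattering amplitude normalized to 800 nm (mm^-1) and `b` the
#' dimensionless scattering power.
#'
#' @param a scattering amplitude at 800 nm, mm^-1
#' @param b scattering power
#' @param wavelength wavelength in nm (> 0, vectorized)
#' @return reduced scattering coefficient, mm^-1
#' @export
scatter_power_law <- function(a, b, wavelength) {
  if (any(!is.finite(a)) || any(a <= 0)) stop("scattering amplitude must be positive")
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) stop("wavelength must be positive")
  a * (wavelength / 800)^(-b)
}

#' Fit the scattering power law to per-wavelength reduced scattering
#'
#' Least-squares fit in log-log space: \eqn{\log \mu_s'} is linear in
#' \eqn{\log(\lambda/800)} with slope \eqn{-b} and intercept \eqn{\log a}.
#' Exact for inputs lying on a power law; at 4 wavelengths the difference
#' from a nonlinear fit is negligible and the log-space fit is
#' deterministic and closed-form.
#'
#' @param wavelengths wavelengths in nm (>= 2 distinct values)
#' @param musp reduced scattering values, mm^-1 (all > 0)
#' @return list with components `a` (mm^-1) and `b`
#' @export
fit_power_law <- function(wavelengths, musp) {
  if (length(wavelengths) < 2 || length(unique(wavelengths)) < 2) {
    stop("need at least 2 distinct wavelengths")
  }
  if (length(musp) != length(wavelengths)) stop("length mismatch")
  if (any(!is.finite(musp)) || any(musp <= 0)) stop("musp must be positive")
  fit <- .fit_power_law_mat(wavelengths, matrix(musp, nrow = 1))
  list(a = fit$a[1], b = fit$b[1])
}

## Vectorized power-law fit: Y is n_obs x n_wavelength matrix of musp values.
## Closed-form simple linear regression of log(musp) on log(lambda/800).
.fit_power_law_mat <- function(wavelengths, Y) {
  x <- log(wavelengths / 800)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  L <- log(Y)
  ybar <- rowMeans(L)
  slope <- as.vector(L %*% xc) / sxx
  loga <- ybar - slope * mean(x)
  list(a = exp(loga), b = -slope)
}

#' Load a hemoglobin extinction-coefficient table
#'
#' Reads a CSV with columns `wavelength_nm`, `eps_HbO2_per_mm_per_uM`,
#' `eps_HHb_per_mm_per_uM` (units mm^-1 per micromolar). The table shipped
#' with the package covers the four instrument wavelengths
#' (659/691/731/851 nm); its provenance and unit conversion are documented
#' in the file header.
#'
#' @param path CSV path; defaults to the packaged table
#' @return data.frame of class `extinction_table`
#' @export
load_extinction_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hemoglobin_extinction.csv",
                        package = "sfdiresponse", mustWork = TRUE)
  }
  ext <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("wavelength_nm", "eps_HbO2_per_mm_per_uM",
                  "eps_HHb_per_mm_per_uM") %in% names(ext)))
  if (any(ext$eps_HbO2_per_mm_per_uM <= 0) || any(ext$eps_HHb_per_mm_per_uM <= 0)) {
    stop("extinction coefficients must be positive")
  }
  class(ext) <- c("extinction_table", "data.frame")
  ext
}

.ext_lookup <- function(ext, wavelengths, tol = 0.51) {
  idx <- vapply(wavelengths, function(w) {
    i <- which(abs(ext$wavelength_nm - w) <= tol)
    if (length(i) != 1) {
      stop("wavelength ", w, " nm not tabulated in extinction table", call. = FALSE)
    }
    i
  }, integer(1))
  cbind(HbO2 = ext$eps_HbO2_per_mm_per_uM[idx],
        HHb  = ext$eps_HHb_per_mm_per_uM[idx])
}

#' Absorption coefficient from hemoglobin concentrations (Beer's law)
#'
#' \eqn{\mu_a(\lambda) = \varepsilon_{HbO_2}(\lambda)\, ctHbO_2 +
#' \varepsilon_{HHb}(\lambda)\, ctHHb}, linear and additive in the
#' concentrations.
#'
#' @param ctHbO2 oxy-hemoglobin concentration, uM
#' @param ctHHb deoxy-hemoglobin concentration, uM
#' @param wavelength wavelength in nm (must be tabulated in `ext`)
#' @param ext extinction table from [load_extinction_table()]
#' @return absorption coefficient, mm^-1
#' @export
mua_from_chromophores <- function(ctHbO2, ctHHb, wavelength, ext) {
  eps <- .ext_lookup(ext, wavelength)
  as.vector(eps[, "HbO2"] * ctHbO2 + eps[, "HHb"] * ctHHb)
}

#' Fit hemoglobin concentrations to a per-wavelength absorption spectrum
#'
#' Non-negativity-constrained linear least squares of the measured
#' \eqn{\mu_a(\lambda)} against the two extinction spectra. Concentrations
#' are physical quantities, so a negative unconstrained solution is clamped
#' to the boundary (the offending concentration set to zero and the other
#' refit). Composites are computed per their definitions:
#' ctTHb = ctHbO2 + ctHHb and StO2 = ctHbO2/ctTHb (undefined when
#' ctTHb = 0, flagged via `sto2_defined`).
#'
#' @param wavelengths wavelengths in nm (>= 2 distinct, tabulated in `ext`)
#' @param mua absorption coefficients, mm^-1
#' @param ext extinction table
#' @return list with `ctHbO2`, `ctHHb`, `ctTHb`, `StO2`, `sto2_defined`
#' @export
fit_chromophores <- function(wavelengths, mua, ext) {
  if (length(wavelengths) < 2 || length(unique(wavelengths)) < 2) {
    stop("need at least 2 distinct wavelengths")
  }
  if (length(mua) != length(wavelengths)) stop("length mismatch")
  fit <- .fit_chromophores_mat(wavelengths, matrix(mua, nrow = 1), ext)
  lapply(fit, function(v) v[1])
}

## Vectorized NNLS for the 2-chromophore design: unconstrained 2x2 normal
## equations, then active-set clamping of negative components. M is
## n_obs x n_wavelength matrix of mua values.
.fit_chromophores_mat <- function(wavelengths, M, ext) {
  E <- .ext_lookup(ext, wavelengths)      # n_wl x 2
  G <- crossprod(E)                       # 2 x 2 Gram
  det_g <- G[1, 1] * G[2, 2] - G[1, 2]^2
  if (det_g <= .Machine$double.eps * G[1, 1] * G[2, 2]) {
    stop("singular chromophore design (wavelengths do not separate spectra)")
  }
  b1 <- as.vector(M %*% E[, 1])
  b2 <- as.vector(M %*% E[, 2])
  c1 <- (G[2, 2] * b1 - G[1, 2] * b2) / det_g
  c2 <- (G[1, 1] * b2 - G[1, 2] * b1) / det_g
  ## clamp: if one component negative, solve the 1-D problem for the other
  neg1 <- c1 < 0
  neg2 <- c2 < 0
  c1[neg1] <- 0
  c2[neg1] <- pmax(0, b2[neg1] / G[2, 2])
  c2[neg2 & !neg1] <- 0
  c1[neg2 & !neg1] <- pmax(0, b1[neg2 & !neg1] / G[1, 1])
  ctTHb <- c1 + c2
  defined <- ctTHb > 0
  StO2 <- ifelse(defined, c1 / ctTHb, NA_real_)
  list(ctHbO2 = c1, ctHHb = c2, ctTHb = ctTHb, StO2 = StO2,
       sto2_defined = defined)
}
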