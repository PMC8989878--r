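#' Build a two-frequency lookup table for one wavelength
#'
#' Tabulates the forward diffusion-model diffuse reflectance over a grid of
#' optical properties at the two instrument frequencies. The absorption axis
#' is log-spaced (Rd varies roughly logarithmically in mua) and the reduced
#' scattering axis is linear. The default ranges bracket the calibration
#' phantom and the simulated tumor/normal tissue values.
#'
#' @param wavelength nm (metadata only; the homogeneous model is achromatic
#'   given the properties)
#' @param fx_pair the two spatial frequencies, mm^-1
#' @param n_rel relative refractive index
#' @param mua_range,musp_range grid ranges, mm^-1
#' @param n_mua,n_musp grid sizes (>= 50 by default)
#' @return list of class `sfdi_lut` with `rd0_surface` and `rd1_surface`
#'   matrices (mua along rows, musp along columns)
#' @export
build_lut <- function(wavelength, fx_pair = c(0, 0.1), n_rel = 1.4,
                      mua_range = c(0.001, 0.5), musp_range = c(0.2, 3.5),
                      n_mua = 60, n_musp = 60) {
  stopifnot(all(mua_range > 0), all(musp_range > 0),
            n_mua >= 2, n_musp >= 2, length(fx_pair) == 2)
  mua_grid <- exp(seq(log(mua_range[1]), log(mua_range[2]), length.out = n_mua))
  musp_grid <- seq(musp_range[1], musp_range[2], length.out = n_musp)
  MU <- matrix(mua_grid, n_mua, n_musp)
  MS <- matrix(musp_grid, n_mua, n_musp, byrow = TRUE)
  rd0 <- .rd_diffusion(MU, MS, fx_pair[1], n_rel)
  rd1 <- .rd_diffusion(MU, MS, fx_pair[2], n_rel)
  structure(list(wavelength = wavelength, mua_grid = mua_grid,
                 musp_grid = musp_grid, rd0_surface = rd0, rd1_surface = rd1,
                 fx_pair = fx_pair, n_rel = n_rel),
            class = "sfdi_lut")
}

#' Serialize / restore a lookup table
#'
#' The LUT is written as a single JSON container holding the grid header
#' (wavelength, frequency pair, refractive index) and the full-precision
#' reflectance surfaces; the round trip is lossless.
#'
#' @param lut an `sfdi_lut`
#' @param path file path
#' @export
write_lut <- function(lut, path) {
  obj <- unclass(lut)
  obj$rd0_surface <- as.vector(obj$rd0_surface)
  obj$rd1_surface <- as.vector(obj$rd1_surface)
  obj$dim <- c(length(lut$mua_grid), length(lut$musp_grid))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dim
  structure(list(wavelength = obj$wavelength, mua_grid = obj$mua_grid,
                 musp_grid = obj$musp_grid,
                 rd0_surface = matrix(obj$rd0_surface, d[1], d[2]),
                 rd1_surface = matrix(obj$rd1_surface, d[1], d[2]),
                 fx_pair = obj$fx_pair, n_rel = obj$n_rel),
            class = "sfdi_lut")
}

## Vectorized inversion of (rd0, rd1) pairs against the forward model
## underlying `lut`. Newton iteration in (log mua, log musp) with numeric
## Jacobian, seeded at the grid center; pixels that fail to converge are
## re-seeded from the nearest node of a coarse LUT subgrid. Returns mua,
## musp, and a validity flag (converged and inside the grid ranges).
.invert_rd_pairs <- function(rd0, rd1, lut, tol = 1e-9, max_iter = 30) {
  m <- length(rd0)
  fx <- lut$fx_pair
  n_rel <- lut$n_rel
  lo <- c(log(min(lut$mua_grid)), log(min(lut$musp_grid)))
  hi <- c(log(max(lut$mua_grid)), log(max(lut$musp_grid)))

  newton <- function(la, ls, idx, iters) {
    for (it in seq_len(iters)) {
      mua <- exp(la); musp <- exp(ls)
      f0 <- .rd_diffusion(mua, musp, fx[1], n_rel) - rd0[idx]
      f1 <- .rd_diffusion(mua, musp, fx[2], n_rel) - rd1[idx]
      h <- 1e-6
      d0a <- (.rd_diffusion(exp(la + h), musp, fx[1], n_rel) -
              .rd_diffusion(exp(la - h), musp, fx[1], n_rel)) / (2 * h)
      d1a <- (.rd_diffusion(exp(la + h), musp, fx[2], n_rel) -
              .rd_diffusion(exp(la - h), musp, fx[2], n_rel)) / (2 * h)
      d0s <- (.rd_diffusion(mua, exp(ls + h), fx[1], n_rel) -
              .rd_diffusion(mua, exp(ls - h), fx[1], n_rel)) / (2 * h)
      d1s <- (.rd_diffusion(mua, exp(ls + h), fx[2], n_rel) -
              .rd_diffusion(mua, exp(ls - h), fx[2], n_rel)) / (2 * h)
      det <- d0a * d1s - d0s * d1a
      det[abs(det) < 1e-300] <- NA
      da <- (-f0 * d1s + f1 * d0s) / det
      ds <- (-d0a * f1 + d1a * f0) / det
      ## damp steps to one log-unit to keep iterates in the model's domain
      step <- pmax(abs(da), abs(ds))
      scale <- ifelse(step > 1, 1 / step, 1)
      da <- da * scale; ds <- ds * scale
      da[is.na(da)] <- 0; ds[is.na(ds)] <- 0
      la <- pmin(pmax(la + da, lo[1] - 2), hi[1] + 2)
      ls <- pmin(pmax(ls + ds, lo[2] - 2), hi[2] + 2)
      if (it %% 5 == 0 || it == iters) {
        res <- pmax(abs(f0), abs(f1))
        if (all(res < tol, na.rm = TRUE)) break
      }
    }
    mua <- exp(la); musp <- exp(ls)
    res0 <- abs(.rd_diffusion(mua, musp, fx[1], n_rel) - rd0[idx])
    res1 <- abs(.rd_diffusion(mua, musp, fx[2], n_rel) - rd1[idx])
    list(la = la, ls = ls, res = pmax(res0, res1))
  }

  finite <- is.finite(rd0) & is.finite(rd1) & rd0 > 0 & rd1 > 0
  la <- rep(mean(c(lo[1], hi[1])), m)
  ls <- rep(mean(c(lo[2], hi[2])), m)
  out_mua <- rep(NA_real_, m); out_musp <- rep(NA_real_, m)
  valid <- rep(FALSE, m)
  idx <- which(finite)
  if (length(idx)) {
    fit <- newton(la[idx], ls[idx], idx, max_iter)
    conv_tol <- 1e-7
    bad <- which(fit$res > conv_tol | !is.finite(fit$res))
    if (length(bad)) {
      ## coarse-grid re-seed for stragglers
      ci <- round(seq(1, length(lut$mua_grid), length.out = 12))
      cj <- round(seq(1, length(lut$musp_grid), length.out = 12))
      c0 <- as.vector(lut$rd0_surface[ci, cj])
      c1 <- as.vector(lut$rd1_surface[ci, cj])
      cla <- log(rep(lut$mua_grid[ci], times = length(cj)))
      cls <- log(rep(lut$musp_grid[cj], each = length(ci)))
      gidx <- idx[bad]
      near <- vapply(seq_along(gidx), function(q) {
        which.min((c0 - rd0[gidx[q]])^2 + (c1 - rd1[gidx[q]])^2)
      }, integer(1))
      refit <- newton(cla[near], cls[near], gidx, max_iter)
      fit$la[bad] <- refit$la; fit$ls[bad] <- refit$ls; fit$res[bad] <- refit$res
    }
    mua <- exp(fit$la); musp <- exp(fit$ls)
    ok <- fit$res <= conv_tol &
      mua >= min(lut$mua_grid) & mua <= max(lut$mua_grid) &
      musp >= min(lut$musp_grid) & musp <= max(lut$musp_grid)
    ok[is.na(ok)] <- FALSE
    out_mua[idx] <- mua; out_musp[idx] <- musp
    valid[idx] <- ok
  }
  list(mua = out_mua, musp = out_musp, valid = valid)
}

#' Invert diffuse reflectance maps to per-pixel optical properties
#'
#' Maps each pixel's (Rd at fx = 0, Rd at the AC frequency) pair back to
#' (mua, musp) by solving the two-frequency forward model: a damped Newton
#' iteration on the log-property plane seeded from the lookup table.
#' Pixels whose Rd pair lies outside the attainable set of the forward
#' model over the LUT grid (e.g. an unphysically high AC reflectance) are
#' flagged invalid rather than extrapolated.
#'
#' @param rd an `sfdi_rd` with both frequency channels per wavelength
#' @param luts named list of `sfdi_lut`, one per wavelength (names are the
#'   wavelengths)
#' @return list of class `sfdi_props`: arrays `mua`, `musp`
#'   `[x, y, wavelength]` and a validity array of the same shape
#' @export
invert_maps <- function(rd, luts) {
  stopifnot(inherits(rd, "sfdi_rd"))
  if (dim(rd$rd)[4] != 2) stop("both frequency channels are required")
  n <- rd$n_px
  wl <- rd$wavelengths
  mua <- array(NA_real_, c(n, n, length(wl)))
  musp <- array(NA_real_, c(n, n, length(wl)))
  valid <- array(FALSE, c(n, n, length(wl)))
  for (k in seq_along(wl)) {
    lut <- luts[[as.character(wl[k])]]
    if (is.null(lut)) stop("no LUT supplied for wavelength ", wl[k])
    inv <- .invert_rd_pairs(as.vector(rd$rd[, , k, 1]),
                            as.vector(rd$rd[, , k, 2]), lut)
    mua[, , k] <- inv$mua
    musp[, , k] <- inv$musp
    valid[, , k] <- matrix(inv$valid, n, n) & rd$valid
  }
  structure(list(mua = mua, musp = musp, valid = valid,
                 wavelengths = wl, n_px = n),
            class = "sfdi_props")
}
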