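# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: the Monte Carlo walker checks the diffusion
# forward model, the grid searches check the closed-form fits, and the
# brute-force discriminant checks the LDA implementation.

# Monte Carlo photon random walk for the total (fx = 0) diffuse reflectance
# of a semi-infinite medium, using the reduced (isotropic-scattering)
# similarity transport: step ~ Exp(mua + musp'), weight *= albedo' at each
# interaction, unpolarized Fresnel reflection at the refractive-index
# mismatched boundary (n_in = n_rel, n_out = 1). Specular entry is excluded
# (photons start just inside traveling downward), matching the calibrated
# measurement convention.
mc_diffuse_reflectance <- function(mua, musp, n_rel = 1.4,
                                   n_photons = 2e5, seed = 42) {
  set.seed(seed)
  mut <- mua + musp
  albedo <- musp / mut
  fresnel <- function(ci) {
    # ci: cos(theta_i) in the dense medium (n_rel) against n = 1
    si <- sqrt(pmax(0, 1 - ci^2))
    st <- n_rel * si                 # Snell: n_in sin(i) = n_out sin(t)
    r <- numeric(length(ci))
    tir <- st >= 1
    r[tir] <- 1
    ct <- sqrt(pmax(0, 1 - st[!tir]^2))
    cii <- ci[!tir]
    rs <- ((n_rel * cii - ct) / (n_rel * cii + ct))^2
    rp <- ((n_rel * ct - cii) / (n_rel * ct + cii))^2
    r[!tir] <- (rs + rp) / 2
    r
  }
  z <- rep(1e-9, n_photons)
  uz <- rep(1, n_photons)
  w <- rep(1, n_photons)
  refl <- 0
  alive <- rep(TRUE, n_photons)
  for (it in 1:100000) {
    idx <- which(alive)
    if (!length(idx)) break
    s <- stats::rexp(length(idx), mut)
    znew <- z[idx] + uz[idx] * s
    hit <- znew < 0
    hidx <- idx[hit]
    if (length(hidx)) {
      ci <- -uz[hidx]
      R <- fresnel(ci)
      u <- stats::runif(length(hidx))
      esc <- u >= R
      refl <- refl + sum(w[hidx][esc])
      alive[hidx[esc]] <- FALSE
      # reflected photons: mirror at z = 0 and finish the step inward
      hb <- hidx[!esc]
      if (length(hb)) {
        z[hb] <- -(z[hb] + uz[hb] * s[hit][!esc])
        uz[hb] <- -uz[hb]
      }
    }
    nidx <- idx[!hit]
    if (length(nidx)) z[nidx] <- znew[!hit]
    # interaction at the end of the step: absorb and scatter isotropically
    sidx <- which(alive)
    w[sidx] <- w[sidx] * albedo
    uz[sidx] <- stats::runif(length(sidx), -1, 1)
    # Russian roulette
    low <- alive & w < 1e-4
    if (any(low)) {
      kill <- stats::runif(sum(low)) > 0.1
      li <- which(low)
      alive[li[kill]] <- FALSE
      w[li[!kill]] <- w[li[!kill]] * 10
    }
  }
  refl / n_photons
}

# Brute-force Gaussian equal-covariance discriminant computed from scratch
# (explicit densities, no shared code with lda_train/lda_predict).
brute_force_lda_predict <- function(train_x, train_y, test_x, priors = NULL) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  classes <- sort(unique(as.character(train_y)))
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  p <- ncol(train_x)
  mus <- lapply(classes, function(cl) colMeans(train_x[train_y == cl, , drop = FALSE]))
  pooled <- Reduce(`+`, lapply(classes, function(cl) {
    xc <- scale(train_x[train_y == cl, , drop = FALSE], scale = FALSE)
    crossprod(xc)
  })) / (nrow(train_x) - length(classes))
  loglik <- sapply(seq_along(classes), function(j) {
    apply(test_x, 1, function(xx) {
      d <- xx - mus[[j]]
      -0.5 * as.numeric(t(d) %*% solve(pooled) %*% d) + log(priors[j])
    })
  })
  loglik <- matrix(loglik, ncol = length(classes))
  classes[apply(loglik, 1, which.max)]
}

# Per-pixel three-point sinusoid least-squares fit: recovers (A, B) from
# I_i = A + B cos(phi0 + theta_i) by fitting A + C cos(theta) + S sin(theta).
sine_fit_envelope <- function(I, phases_deg) {
  th <- phases_deg * pi / 180
  X <- cbind(1, cos(th), sin(th))
  cf <- solve(X, I)
  c(dc = cf[1], ac = sqrt(cf[2]^2 + cf[3]^2))
}

# Log-space SSE grid search for the scattering power law.
grid_search_power_law <- function(wavelengths, musp,
                                  a_range = c(0.5, 3), b_range = c(0, 3),
                                  n_grid = 400) {
  a_grid <- seq(a_range[1], a_range[2], length.out = n_grid)
  b_grid <- seq(b_range[1], b_range[2], length.out = n_grid)
  best <- c(NA, NA); best_sse <- Inf
  for (b in b_grid) {
    pred0 <- (wavelengths / 800)^(-b)
    sse <- vapply(a_grid, function(a) sum((log(musp) - log(a * pred0))^2),
                  numeric(1))
    i <- which.min(sse)
    if (sse[i] < best_sse) { best_sse <- sse[i]; best <- c(a_grid[i], b) }
  }
  list(a = best[1], b = best[2])
}

# Non-negative grid search for the two-chromophore Beer's-law fit.
grid_search_chromophores <- function(wavelengths, mua, ext,
                                     c_max = 100, n_grid = 500) {
  eps <- sfdiresponse:::.ext_lookup(ext, wavelengths)
  cg <- seq(0, c_max, length.out = n_grid)
  best <- c(NA, NA); best_sse <- Inf
  for (c2 in cg) {
    resid <- outer(mua - eps[, "HHb"] * c2, rep(1, n_grid)) -
      outer(eps[, "HbO2"], cg)
    sse <- colSums(resid^2)
    i <- which.min(sse)
    if (sse[i] < best_sse) { best_sse <- sse[i]; best <- c(cg[i], c2) }
  }
  list(ctHbO2 = best[1], ctHHb = best[2])
}
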