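make_raw <- function(frames, fx = c(0, 0.1), wl = 659, pitch = 0.5) {
  structure(list(frames = frames, wavelengths = wl, fx = fx,
                 phases = c(0, 120, 240), pixel_pitch_mm = pitch,
                 meta = list()), class = "sfdi_raw")
}

test_that("three-phase demodulation is exact on analytic sinusoids", {
  n <- 16
  th <- c(0, 120, 240) * pi / 180
  set.seed(11)
  for (rep in 1:20) {
    A <- matrix(stats::runif(n * n, 0.2, 0.8), n)
    B <- matrix(stats::runif(n * n, 0.05, 0.3), n)
    phi0 <- stats::runif(1, 0, 2 * pi)
    fr <- array(NA_real_, c(n, n, 1, 2, 3))
    for (p in 1:3) {
      fr[, , 1, 1, p] <- A
      fr[, , 1, 2, p] <- A + B * cos(phi0 + th[p])
    }
    dem <- demodulate(make_raw(fr))
    expect_equal(dem$m_ac[, , 1], B, tolerance = 1e-12)
    expect_equal(dem$m_dc[, , 1], A, tolerance = 1e-12)
  }
  ## constant frames demodulate to zero AC amplitude
  fr <- array(0.37, c(4, 4, 1, 2, 3))
  dem <- demodulate(make_raw(fr))
  expect_true(all(dem$m_ac == 0))
  expect_equal(as.vector(dem$m_dc), rep(0.37, 16), tolerance = 1e-12)
})

test_that("demodulation matches a per-pixel sine-fit oracle", {
  n <- 6
  set.seed(12)
  fr <- array(stats::runif(n * n * 6, 0.1, 1), c(n, n, 1, 2, 3))
  dem <- demodulate(make_raw(fr))
  for (i in 1:n) for (j in 1:n) {
    o <- sine_fit_envelope(fr[i, j, 1, 2, ], c(0, 120, 240))
    expect_equal(dem$m_ac[i, j, 1], unname(o["ac"]), tolerance = 1e-10)
  }
})

test_that("demodulation validates its inputs", {
  fr <- array(0.5, c(4, 4, 1, 2, 2))
  expect_error(demodulate(make_raw(fr)), "3 phase")
  fr2 <- array(0.5, c(4, 4, 1, 2, 3)); fr2[1, 1, 1, 1, 1] <- NA
  expect_error(demodulate(make_raw(fr2)), "non-finite")
})

test_that("calibration removes the system response", {
  inst <- instrument_model(n_px = 24, noise_frac = 0)
  cal <- calibration_phantom_props()
  ref <- reference_phantom_props()
  dem_ref <- demodulate(simulate_raw_images(make_phantom_scene(ref, inst), inst))
  ## self-calibration returns the model reflectance of the reference
  rd_self <- calibrate(dem_ref, dem_ref, ref, inst$n_rel)
  for (k in 1:4) {
    expect_equal(rd_self$rd[, , k, 1],
                 matrix(sfd_reflectance(ref$mua[k], ref$musp[k], 0), 24, 24),
                 tolerance = 1e-10)
  }
  ## phantom with the printed 851 nm properties calibrated against the
  ## second phantom recovers the model value within 1%
  dem_cal <- demodulate(simulate_raw_images(make_phantom_scene(cal, inst), inst))
  rd <- calibrate(dem_cal, dem_ref, ref, inst$n_rel)
  k851 <- which(inst$wavelengths == 851)
  expect_equal(mean(rd$rd[, , k851, 1]),
               sfd_reflectance(0.0074, 0.893, 0), tolerance = 0.01)
  expect_equal(mean(rd$rd[, , k851, 2]),
               sfd_reflectance(0.0074, 0.893, 0.1), tolerance = 0.01)
  ## doubling both sample and reference gain leaves Rd unchanged
  dem_cal2 <- dem_cal; dem_ref2 <- dem_ref
  dem_cal2$m_dc <- 2 * dem_cal$m_dc; dem_cal2$m_ac <- 2 * dem_cal$m_ac
  dem_ref2$m_dc <- 2 * dem_ref$m_dc; dem_ref2$m_ac <- 2 * dem_ref$m_ac
  rd2 <- calibrate(dem_cal2, dem_ref2, ref, inst$n_rel)
  expect_equal(rd$rd, rd2$rd, tolerance = 1e-12)
})

test_that("in-frame drift correction recovers the undrifted maps", {
  inst <- instrument_model(n_px = 24, noise_frac = 0)
  cal <- calibration_phantom_props()
  ref <- reference_phantom_props()
  sc <- make_phantom_scene(cal, inst)
  mask <- matrix(FALSE, 24, 24); mask[2:7, 2:7] <- TRUE
  dem_ref <- demodulate(simulate_raw_images(make_phantom_scene(ref, inst), inst))
  session_ref <- t(sapply(1:4, function(k) {
    c(sfd_reflectance(cal$mua[k], cal$musp[k], 0),
      sfd_reflectance(cal$mua[k], cal$musp[k], 0.1))
  }))
  rd_clean <- calibrate(demodulate(simulate_raw_images(sc, inst)), dem_ref, ref)
  raw_drift <- simulate_raw_images(sc, inst, drift_gain = 1.05)
  rd_drift <- calibrate(demodulate(raw_drift), dem_ref, ref)
  corrected <- drift_correct(rd_drift, mask, session_ref)
  ## 5% injected drift: corrected maps within 0.5% of the no-drift run
  expect_lt(max(abs(corrected$rd / rd_clean$rd - 1)), 0.005)
  ## no drift: factors are 1
  c0 <- drift_correct(rd_clean, mask, session_ref)
  expect_equal(as.vector(attr(c0, "drift_factors")), rep(1, 8),
               tolerance = 1e-9)
  ## correction is a uniform scale: pixel ratios unchanged
  r1 <- corrected$rd[1, 1, 1, 1] / corrected$rd[10, 10, 1, 1]
  r2 <- rd_drift$rd[1, 1, 1, 1] / rd_drift$rd[10, 10, 1, 1]
  expect_equal(r1, r2, tolerance = 1e-12)
  ## in-frame mean equals the session reference exactly after correction
  expect_equal(mean(corrected$rd[, , 2, 1][mask]), session_ref[2, 1],
               tolerance = 1e-12)
  expect_warning(drift_correct(rd_drift, matrix(FALSE, 24, 24), session_ref),
                 "skipped")
})

test_that("surface correction inverts the generative height/angle model", {
  ext <- default_ext()
  inst <- instrument_model(n_px = 48, noise_frac = 0)
  ref <- reference_phantom_props()
  bg <- list(a = 1.0, b = 1.3, ctHbO2 = 30, ctHHb = 15)
  bm <- list(a = 1.4, b = 1.1, ctHbO2 = 60, ctHHb = 40)
  dem_ref <- demodulate(simulate_raw_images(make_phantom_scene(ref, inst), inst))
  sc <- make_tumor_scene(bm, 250, bg, calibration_phantom_props(), inst, ext)
  rd <- calibrate(demodulate(simulate_raw_images(sc, inst)), dem_ref, ref)
  cor <- surface_correct(rd, sc$height_mm, sc$angle_deg,
                         inst$height_gain_per_mm)
  ## flat scene with the same tumor properties everywhere, as reference
  flat <- sc; flat$height_mm[] <- 0; flat$angle_deg[] <- 0
  rd_flat <- calibrate(demodulate(simulate_raw_images(flat, inst)), dem_ref, ref)
  ok <- cor$valid
  for (k in c(1, 4)) {
    expect_lt(max(abs(cor$rd[, , k, 1][ok] / rd_flat$rd[, , k, 1][ok] - 1)),
              0.01)
  }
  ## the 40-degree mask removes the cap rim: surviving pixels are exactly
  ## those the scene geometry puts at or below 40 degrees
  expect_equal(cor$valid[sc$tumor_mask], sc$angle_deg[sc$tumor_mask] <= 40)
  ## flat input is returned unchanged
  z <- matrix(0, 48, 48)
  cor_flat <- surface_correct(rd, z, z, inst$height_gain_per_mm)
  expect_equal(cor_flat$rd, rd$rd)
  ## corrections never resurrect invalid pixels
  rd_bad <- rd; rd_bad$valid[1, 1] <- FALSE
  cor_bad <- surface_correct(rd_bad, z, z, inst$height_gain_per_mm)
  expect_false(cor_bad$valid[1, 1])
})
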