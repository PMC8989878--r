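test_that("phantom scenes are homogeneous, flat and deterministic", {
  inst <- instrument_model(n_px = 32)
  props <- calibration_phantom_props()
  sc <- make_phantom_scene(props, inst)
  expect_equal(dim(sc$mua), c(32, 32, 4))
  for (k in 1:4) {
    expect_true(all(sc$mua[, , k] == props$mua[k]))
    expect_true(all(sc$musp[, , k] == props$musp[k]))
  }
  expect_true(all(sc$height_mm == 0) && all(sc$angle_deg == 0))
  expect_identical(sc, make_phantom_scene(props, inst))
})

test_that("tumor scene geometry follows the spherical cap model", {
  inst <- instrument_model(n_px = 128, pixel_pitch_mm = 0.25)
  ext <- default_ext()
  bm <- list(a = 1.2, b = 1.3, ctHbO2 = 60, ctHHb = 40)
  bg <- list(a = 1.0, b = 1.3, ctHbO2 = 30, ctHHb = 15)
  sc <- make_tumor_scene(bm, 250, bg, calibration_phantom_props(), inst, ext)
  r_mm <- (3 * 250 / (2 * pi))^(1 / 3)
  ## analytic fraction of cap-footprint pixels with surface angle <= 40 deg
  ## is sin^2(40 deg)
  frac <- mean(sc$angle_deg[sc$tumor_mask] <= 40)
  expect_equal(frac, sin(40 * pi / 180)^2, tolerance = 0.02)
  ## rim angle approaches 90 degrees, apex is flat
  expect_gt(max(sc$angle_deg[sc$tumor_mask]), 85)
  expect_lt(min(sc$angle_deg[sc$tumor_mask]), 5)
  ## height map is the cap: apex height equals the radius
  expect_equal(max(sc$height_mm), r_mm, tolerance = 0.02)
  expect_false(any(sc$tumor_mask & sc$inframe_mask))
})

test_that("degenerate tumors vanish and absorption scales linearly with hemoglobin", {
  inst <- instrument_model(n_px = 48)
  ext <- default_ext()
  bg <- list(a = 1.0, b = 1.3, ctHbO2 = 30, ctHHb = 15)
  ph <- calibration_phantom_props()
  bm <- list(a = 1.4, b = 1.1, ctHbO2 = 50, ctHHb = 30)
  ## volume -> 0: no cap pixels, scene equals the background scene
  sc0 <- make_tumor_scene(bm, 0.01, bg, ph, inst, ext)
  sc_bg <- make_tumor_scene(bg, 0.01, bg, ph, inst, ext)
  expect_false(any(sc0$tumor_mask))
  expect_equal(sc0$mua, sc_bg$mua)
  ## doubling both hemoglobin species doubles mua inside the tumor mask
  sc1 <- make_tumor_scene(bm, 250, bg, ph, inst, ext)
  bm2 <- modifyList(bm, list(ctHbO2 = 100, ctHHb = 60))
  sc2 <- make_tumor_scene(bm2, 250, bg, ph, inst, ext)
  m <- sc1$tumor_mask
  for (k in 1:4) {
    expect_equal(sc2$mua[, , k][m], 2 * sc1$mua[, , k][m], tolerance = 1e-12)
  }
  ## oversized footprint is rejected
  expect_error(make_tumor_scene(bm, 1e5, bg, ph, inst, ext), "field of view")
})

test_that("raw image simulation is consistent with demodulation and reproducible", {
  inst <- instrument_model(n_px = 24, noise_frac = 0)
  props <- calibration_phantom_props()
  sc <- make_phantom_scene(props, inst)
  raw <- simulate_raw_images(sc, inst, seed = 5)
  dem <- demodulate(raw)
  for (k in 1:4) {
    rd0 <- sfd_reflectance(props$mua[k], props$musp[k], 0, inst$n_rel)
    rd1 <- sfd_reflectance(props$mua[k], props$musp[k], 0.1, inst$n_rel)
    ## three-phase demodulation returns mtf * Rd(0.1)/2 * gain pointwise
    expect_equal(dem$m_ac[, , k], inst$mtf_ac * rd1 / 2 * inst$gain_map,
                 tolerance = 1e-9)
    expect_equal(dem$m_dc[, , k], rd0 * inst$gain_map, tolerance = 1e-9)
  }
  expect_identical(raw$frames, simulate_raw_images(sc, inst, seed = 5)$frames)
})

test_that("simulated noise matches the configured sigma", {
  inst <- instrument_model(n_px = 8, noise_frac = 0.02)
  props <- calibration_phantom_props()[1, , drop = FALSE]
  inst$wavelengths <- 659
  sc <- make_phantom_scene(props, inst)
  reps <- sapply(1:120, function(i) {
    simulate_raw_images(sc, inst, seed = 1000 + i)$frames[, , 1, 1, 1]
  })
  dc <- inst$gain_map * sfd_reflectance(props$mua, props$musp, 0, inst$n_rel)
  ratio <- apply(reps, 1, stats::sd) / (0.02 * as.vector(dc))
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("the default cohort matches the study design", {
  cfg <- cohort_config(seed = 3)
  coh <- fixture("design_cohort", generate_cohort(cfg, render = FALSE))
  expect_equal(nrow(coh$subjects), 26)
  expect_equal(as.vector(table(coh$subjects$group)[c("Control", "CPA", "CPA+Ab")]),
               c(3, 9, 14))
  tr <- coh$truth
  expect_equal(sum(tr$day == 0), 26)
  ## all Controls gone after Day 12
  expect_equal(nrow(tr[tr$group == "Control" & tr$day > 12, ]), 0)
  ## about half of each treated arm leaves at Day 12
  late <- tr[tr$day == 30, ]
  expect_equal(sum(late$group == "CPA"), 9 - floor(9 / 2))
  expect_equal(sum(late$group == "CPA+Ab"), 14 - floor(14 / 2))
  ## schedule: no off-schedule days, no records past dropout
  expect_true(all(tr$day %in% cfg$days))
  for (s in coh$subjects$subject) {
    dd <- coh$subjects$dropout_day[coh$subjects$subject == s]
    expect_true(all(tr$day[tr$subject == s] <= dd))
  }
})

test_that("cohort generation is seed-deterministic and render-invariant at truth level", {
  cfg <- cohort_config(n_per_group = c(Control = 2, CPA = 2, `CPA+Ab` = 2),
                       days = c(0, 3, 5),
                       instrument = instrument_model(n_px = 44), seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$records[[5]]$raw$frames, c2$records[[5]]$raw$frames)
  c3 <- generate_cohort(cfg, render = FALSE)
  expect_identical(c1$truth, c3$truth)
  expect_identical(c1$records[[3]]$caliper, c3$records[[3]]$caliper)
})

test_that("a noise-free cohort reproduces the group-mean anchor curves exactly", {
  cfg <- zero_noise_config(n_px = 32, days = c(0, 3, 5, 6))
  coh <- generate_cohort(cfg, render = FALSE)
  tab <- truth_cohort_table(coh)
  for (g in c("Control", "CPA", "CPA+Ab")) {
    for (v in c("a", "ctHHb", "volume")) {
      anchors <- cfg$trajectories[[g]][[v]]
      sub <- tab[tab$group == g, ]
      for (d in c(0, 3, 5, 6)) {
        expected <- stats::approx(anchors$day, anchors$pct, xout = d, rule = 2)$y
        expect_equal(mean(sub[[paste0("pct_change_", v)]][sub$day == d]),
                     expected, tolerance = 1e-8)
      }
    }
  }
})
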