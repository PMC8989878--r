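test_that("diffuse reflectance obeys physical limits and monotonicity", {
  ## lossless semi-infinite medium returns all light at fx = 0
  expect_equal(suppressWarnings(sfd_reflectance(1e-9, 1.0, 0)), 1,
               tolerance = 1e-3)
  ## strictly decreasing in fx and in mua over a grid of property pairs
  set.seed(1)
  mua <- exp(stats::runif(120, log(0.002), log(0.3)))
  musp <- stats::runif(120, 0.3, 3)
  fx <- c(0, 0.05, 0.1, 0.2)
  rd <- suppressWarnings(
    sapply(fx, function(f) sfd_reflectance(mua, musp, f)))
  expect_true(all(diff(t(rd)) < 0))
  rd_lo <- suppressWarnings(sfd_reflectance(mua, musp, 0.1))
  rd_hi <- suppressWarnings(sfd_reflectance(mua * 1.2, musp, 0.1))
  expect_true(all(rd_hi < rd_lo))
  expect_true(all(rd >= 0 & rd <= 1))
  ## AC reflectance below planar reflectance for any properties
  expect_true(all(rd[, 4] < rd[, 1]))
})

test_that("diffuse reflectance rejects invalid inputs and warns on low albedo", {
  expect_error(sfd_reflectance(-0.01, 1), "positive")
  expect_error(sfd_reflectance(0.01, Inf), "positive")
  expect_error(sfd_reflectance(0.01, 1, fx = -1), "frequency")
  expect_warning(sfd_reflectance(0.5, 1.0), "diffusion")
})

test_that("forward model matches the Monte Carlo photon oracle at the phantom point", {
  ## frozen oracle value: mc_diffuse_reflectance(0.0086, 1.044, 1.4,
  ## n_photons = 5e5, seed = 42) = 0.6477273 (helper-oracles.R)
  rd_mc <- 0.6477273
  rd <- sfd_reflectance(0.0086, 1.044, 0, 1.4)
  expect_lt(abs(rd - rd_mc) / rd_mc, 0.03)
  ## live low-precision oracle run at a second property pair
  rd_mc2 <- mc_diffuse_reflectance(0.02, 1.0, 1.4, n_photons = 3e4, seed = 7)
  expect_lt(abs(sfd_reflectance(0.02, 1.0, 0, 1.4) - rd_mc2) / rd_mc2, 0.05)
})

test_that("scattering power law evaluates and inverts exactly", {
  expect_equal(scatter_power_law(1, 0, 659), 1)
  expect_equal(scatter_power_law(1, 1, 800), 1)
  expect_equal(scatter_power_law(1, 1, 400), 2)
  wl <- c(659, 691, 731, 851)
  fit <- fit_power_law(wl, scatter_power_law(1.2, 1.4, wl))
  expect_equal(fit$a, 1.2, tolerance = 1e-12)
  expect_equal(fit$b, 1.4, tolerance = 1e-12)
  flat <- fit_power_law(wl, rep(0.9, 4))
  expect_equal(flat$a, 0.9, tolerance = 1e-12)
  expect_equal(flat$b, 0, tolerance = 1e-12)
  ## identity property over random parameters
  set.seed(2)
  for (i in 1:40) {
    a <- stats::runif(1, 0.5, 3); b <- stats::runif(1, 0, 3)
    f <- fit_power_law(wl, scatter_power_law(a, b, wl))
    expect_equal(c(f$a, f$b), c(a, b), tolerance = 1e-9)
  }
  expect_error(fit_power_law(800, 1), "2 distinct")
  expect_error(fit_power_law(wl, c(-1, 1, 1, 1)), "positive")
})

test_that("noisy power-law fit agrees with a grid-search oracle", {
  wl <- c(659, 691, 731, 851)
  set.seed(3)
  musp <- scatter_power_law(1.5, 1.2, wl) * exp(stats::rnorm(4, 0, 0.01))
  fit <- fit_power_law(wl, musp)
  ora <- grid_search_power_law(wl, musp)
  ## agreement within the oracle's grid resolution
  expect_equal(fit$a, ora$a, tolerance = 2 * (3 - 0.5) / 400 / ora$a)
  expect_equal(fit$b, ora$b, tolerance = 2 * 3 / 400 / max(ora$b, 1))
})

test_that("Beer's law absorption is linear and additive", {
  ext <- default_ext()
  wl <- c(659, 691, 731, 851)
  expect_equal(mua_from_chromophores(0, 0, wl, ext), rep(0, 4))
  eps <- sfdiresponse:::.ext_lookup(ext, wl)
  expect_equal(mua_from_chromophores(25, 0, wl, ext),
               as.vector(eps[, "HbO2"]) * 25)
  f1 <- mua_from_chromophores(10, 5, wl, ext)
  f2 <- mua_from_chromophores(7, 30, wl, ext)
  expect_equal(f1 + f2, mua_from_chromophores(17, 35, wl, ext))
  expect_error(mua_from_chromophores(1, 1, 500, ext), "not tabulated")
})

test_that("chromophore fit recovers concentrations and composites exactly", {
  ext <- default_ext()
  wl <- c(659, 691, 731, 851)
  fit <- fit_chromophores(wl, mua_from_chromophores(20, 20, wl, ext), ext)
  expect_equal(fit$ctHbO2, 20, tolerance = 1e-10)
  expect_equal(fit$ctHHb, 20, tolerance = 1e-10)
  expect_equal(fit$StO2, 0.5, tolerance = 1e-10)
  expect_equal(fit$ctTHb, fit$ctHbO2 + fit$ctHHb)
  ## identity property over random non-negative concentrations
  set.seed(4)
  for (i in 1:40) {
    c1 <- stats::runif(1, 0, 90); c2 <- stats::runif(1, 0, 90)
    f <- fit_chromophores(wl, mua_from_chromophores(c1, c2, wl, ext), ext)
    expect_equal(c(f$ctHbO2, f$ctHHb), c(c1, c2), tolerance = 1e-8)
    expect_equal(f$ctTHb, f$ctHbO2 + f$ctHHb)
    if (f$ctTHb > 0) expect_equal(f$StO2, f$ctHbO2 / f$ctTHb)
  }
  ## zero absorption: zero concentrations, saturation undefined
  z <- fit_chromophores(wl, rep(0, 4), ext)
  expect_equal(c(z$ctHbO2, z$ctHHb), c(0, 0))
  expect_false(z$sto2_defined)
  expect_true(is.na(z$StO2))
  expect_error(fit_chromophores(c(659, 659), c(1, 1), ext), "2 distinct")
})

test_that("negative unconstrained solutions clamp to the boundary like the grid oracle", {
  ext <- default_ext()
  wl <- c(659, 691, 731, 851)
  eps <- sfdiresponse:::.ext_lookup(ext, wl)
  ## spectrum built so the unconstrained HHb coefficient is negative
  mua <- as.vector(eps[, "HbO2"]) * 30 - 0.4 * as.vector(eps[, "HHb"]) * 5
  fit <- fit_chromophores(wl, mua, ext)
  expect_equal(fit$ctHHb, 0)
  expect_gt(fit$ctHbO2, 0)
  ora <- grid_search_chromophores(wl, mua, ext, c_max = 60, n_grid = 601)
  expect_equal(fit$ctHbO2, ora$ctHbO2, tolerance = 0.2 / max(ora$ctHbO2, 1))
  expect_equal(fit$ctHHb, ora$ctHHb, tolerance = 1e-9)
})

test_that("the shipped extinction table covers the instrument wavelengths", {
  ext <- default_ext()
  expect_setequal(ext$wavelength_nm, c(659, 691, 731, 851))
  expect_true(all(ext$eps_HbO2_per_mm_per_uM > 0))
  expect_true(all(ext$eps_HHb_per_mm_per_uM > 0))
  ## unit conversion: 40 uM of deoxy-hemoglobin at 659 nm should give an
  ## absorption in the low tissue range (order 0.01-0.1 mm^-1)
  mua <- mua_from_chromophores(0, 40, 659, ext)
  expect_gt(mua, 0.005); expect_lt(mua, 0.1)
})
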