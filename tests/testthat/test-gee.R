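## Simple clustered longitudinal simulator for estimator checks (no imaging).
sim_long <- function(n_per_group = 6, days = 1:5, effect = 0, noise = 1,
                     groups = c("G1", "G2"), seed = 1) {
  set.seed(seed)
  rows <- expand.grid(day = days, subject_i = seq_len(n_per_group),
                      group = groups, stringsAsFactors = FALSE)
  rows$subject <- paste0(rows$group, rows$subject_i)
  rows$y <- ifelse(rows$group == groups[2], effect * rows$day, 0) +
    stats::rnorm(nrow(rows), 0, noise)
  rows[order(rows$subject, rows$day), ]
}

test_that("GEE with independence working correlation equals ordinary least squares", {
  d <- sim_long(effect = 0.8, seed = 41)
  d$day_f <- factor(d$day); d$group_f <- factor(d$group)
  fit <- gee_fit(y ~ day_f * group_f, d, id = d$subject,
                 corstr = "independence")
  ols <- stats::lm(y ~ day_f * group_f, data = d)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-8)
})

test_that("saturated AR(1) GEE reproduces cell means on balanced data", {
  d <- sim_long(effect = 1.2, seed = 42)
  d$day_f <- factor(d$day); d$group_f <- factor(d$group)
  fit <- gee_fit(y ~ day_f * group_f, d, id = d$subject, corstr = "ar1")
  cells <- aggregate(y ~ day_f + group_f, data = d, FUN = mean)
  pred <- gee_adjusted_means(fit, cells[, c("day_f", "group_f")])
  expect_equal(pred$estimate, cells$y, tolerance = 1e-6)
  expect_true(all(pred$se > 0))
  expect_gte(fit$alpha, -0.95); expect_lte(fit$alpha, 0.95)
})

test_that("null signal gives near-zero day effects and self-contrast is exactly null", {
  d <- sim_long(effect = 0, noise = 0, seed = 43)
  d <- d[d$group == "G1", ]
  d$day_f <- factor(d$day)
  fit <- gee_fit(y ~ day_f, d, id = d$subject, corstr = "ar1")
  expect_equal(max(abs(fit$coefficients)), 0, tolerance = 1e-10)
  ## contrast of a group with itself
  d2 <- sim_long(effect = 1, seed = 44)
  d2$day_f <- factor(d2$day); d2$group_f <- factor(d2$group)
  fit2 <- gee_fit(y ~ day_f * group_f, d2, id = d2$subject)
  ct <- gee_contrast(fit2, rep(0, length(fit2$coefficients)))
  expect_equal(ct$estimate, 0)
  expect_equal(ct$p, 1)
})

test_that("a noise-free cohort yields day-5 adjusted means at the configured anchors", {
  cfg <- zero_noise_config(days = c(0:6, 9, 12))
  coh <- generate_cohort(cfg, render = FALSE)
  tab <- truth_cohort_table(coh)
  fit <- fit_gee(tab, "a", "short")
  nd <- data.frame(day_f = factor(5, levels = fit$xlevels$day_f),
                   group_f = factor(c("Control", "CPA", "CPA+Ab"),
                                    levels = fit$xlevels$group_f))
  am <- gee_adjusted_means(fit, nd)
  expect_equal(am$estimate, c(-10, 9, -10), tolerance = 1e-6)
})

test_that("scattering-amplitude contrasts separate CPA from CPA+Ab from Day 5 under noise", {
  hits <- 0; reps <- 25
  for (i in seq_len(reps)) {
    coh <- generate_cohort(cohort_config(seed = 400 + i), render = FALSE)
    tab <- truth_cohort_table(coh)
    fit <- fit_gee(tab, "a", "short")
    ct <- posthoc_contrasts(fit, days = 5)
    p <- ct$p[ct$group1 == "CPA" & ct$group2 == "CPA+Ab"]
    if (p < 0.007) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("contrast power declines monotonically with noise", {
  pow <- sapply(c(1, 8), function(noise) {
    mean(sapply(1:20, function(i) {
      d <- sim_long(n_per_group = 5, effect = 0.5, noise = noise,
                    seed = 500 + i)
      d$day_f <- factor(d$day); d$group_f <- factor(d$group)
      fit <- gee_fit(y ~ day_f * group_f, d, id = d$subject)
      nd <- data.frame(day_f = factor(5, levels = fit$xlevels$day_f),
                       group_f = factor(c("G1", "G2"),
                                        levels = fit$xlevels$group_f))
      L <- sfdiresponse:::.gee_lincomb(fit, nd)
      gee_contrast(fit, L[1, ] - L[2, ])$p < 0.05
    }))
  })
  expect_gt(pow[1], pow[2])
})

test_that("scope rules are enforced", {
  coh <- generate_cohort(cohort_config(seed = 5), render = FALSE)
  tab <- truth_cohort_table(coh)
  expect_error(fit_gee(tab, "nothere", "short"), "not present")
  one_group <- tab[tab$group == "CPA", ]
  expect_error(fit_gee(one_group, "a", "long"), "two groups")
  fit_long <- fit_gee(tab, "a", "long")
  expect_false("Control" %in% fit_long$groups)
  expect_equal(max(fit_long$days), 30)
  fit_short <- fit_gee(tab, "a", "short")
  expect_equal(max(fit_short$days), 12)
  expect_equal(length(fit_short$groups), 3)
})
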