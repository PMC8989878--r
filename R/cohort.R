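#' Default group-mean trajectory anchors
#'
#' Piecewise-linear group-mean percent-change curves for each biomarker and
#' treatment arm, anchored at the study's characteristic features: the
#' responsive (CPA) arm's scattering amplitude rises to +9% by Day 5 and
#' keeps climbing, while the resistant (CPA+Ab) and untreated Control arms
#' fall to about -10% by Day 5; ctHHb spikes early in the untreated
#' Controls (Days 3-6) then declines, dips slightly early in both treated
#' arms, and climbs to late-study plateaus near +50% (CPA) versus +25%
#' (CPA+Ab); volume grows exponentially in Controls, rises to Day 3 then
#' regresses under CPA, and rises linearly to about Day 9 before stasis
#' under CPA+Ab. Values between anchors are linear interpolation.
#'
#' @return nested list `trajectories[[group]][[biomarker]]` of
#'   data.frames (`day`, `pct`)
#' @export
default_trajectories <- function() {
  an <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(day = m[, 1], pct = m[, 2])
  }
  list(
    Control = list(
      a       = an(0, 0, 3, -4, 5, -10, 9, -12, 12, -14),
      b       = an(0, 0, 12, -4),
      ctHbO2  = an(0, 0, 3, 10, 6, 0, 12, -10),
      ctHHb   = an(0, 0, 3, 40, 5, 60, 6, 55, 9, 35, 12, 15),
      volume  = an(0, 0, 1, 15, 2, 32, 3, 70, 4, 100, 5, 150, 6, 200,
                   9, 400, 12, 700)
    ),
    CPA = list(
      a       = an(0, 0, 1, 0, 3, 3, 5, 9, 9, 18, 12, 25, 21, 35, 30, 45),
      b       = an(0, 0, 30, -10),
      ctHbO2  = an(0, 0, 6, 0, 12, 10, 30, 10),
      ctHHb   = an(0, 0, 3, -5, 5, -5, 6, 0, 9, 15, 12, 30, 15, 40,
                   21, 50, 30, 50),
      volume  = an(0, 0, 3, 40, 5, 28, 6, 12, 9, -25, 12, -50, 30, -70)
    ),
    `CPA+Ab` = list(
      a       = an(0, 0, 1, 0, 3, -6, 5, -10, 9, -13, 12, -15, 21, -18,
                   30, -20),
      b       = an(0, 0, 30, -4),
      ctHbO2  = an(0, 0, 30, 5),
      ctHHb   = an(0, 0, 3, -5, 5, -5, 6, 0, 9, 15, 12, 30, 15, 40,
                   21, 25, 30, 25),
      volume  = an(0, 0, 3, 24, 5, 40, 9, 72, 12, 80, 30, 85)
    )
  )
}

#' Printed optical properties of the calibration phantom
#'
#' The tissue-mimicking calibration phantom's known absorption and reduced
#' scattering at the four instrument wavelengths.
#'
#' @return data.frame with `wavelength`, `mua`, `musp` (mm^-1)
#' @export
calibration_phantom_props <- function() {
  data.frame(wavelength = c(659, 691, 731, 851),
             mua  = c(0.0086, 0.0088, 0.0087, 0.0074),
             musp = c(1.044, 1.014, 0.980, 0.893))
}

#' A second reference phantom with distinct known properties
#'
#' Used as the against-phantom in calibration: flat absorption and a
#' mild scattering power law, deliberately different from the
#' calibration phantom so that calibration is a real system-response
#' removal rather than an identity.
#'
#' @return data.frame with `wavelength`, `mua`, `musp` (mm^-1)
#' @export
reference_phantom_props <- function() {
  wl <- c(659, 691, 731, 851)
  data.frame(wavelength = wl, mua = rep(0.012, 4),
             musp = round(scatter_power_law(1.2, 0.8, wl), 4))
}

#' Cohort configuration (generative ground truth)
#'
#' Bundles everything that defines a simulated longitudinal study: group
#' sizes (Control 3, CPA 9, CPA+Ab 14), the measurement schedule (daily
#' Days 0-6, then every 3 days through Day 30), the dropout plan (all
#' Controls leave by Day 12; about half of each treated arm is euthanized
#' on Day 12 and the remainder on Day 30), baseline biomarker levels with
#' between-subject spread, the group-mean trajectory anchors, the noise
#' model (between-subject trajectory multipliers, day-level biomarker
#' noise, caliper error), the background-tissue and phantom optics, the
#' instrument model, and the seed.
#'
#' @param n_per_group named sizes for Control / CPA / CPA+Ab
#' @param days measurement schedule (must include day 0)
#' @param baseline named list of day-0 group-typical biomarker values:
#'   `volume` (mm^3), `a` (mm^-1), `b`, `ctHbO2`, `ctHHb` (uM)
#' @param baseline_cv lognormal between-subject coefficient of variation of
#'   each baseline value
#' @param subject_sd sd of the per-subject, per-biomarker trajectory
#'   multiplier (mean 1)
#' @param day_noise_sd named day-level additive noise sd on the
#'   percent-change scale
#' @param caliper_cv multiplicative caliper measurement error on L and W
#' @param aspect_mean,aspect_sd per-subject tumor length/width ratio
#' @param background normal-tissue biomarkers outside the tumor
#' @param trajectories anchor curves, see [default_trajectories()]
#' @param instrument an [instrument_model()]
#' @param seed integer RNG seed
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_per_group = c(Control = 3, CPA = 9, `CPA+Ab` = 14),
                          days = c(0:6, seq(9, 30, by = 3)),
                          baseline = list(volume = 250, a = 1.2, b = 1.3,
                                          ctHbO2 = 60, ctHHb = 40),
                          baseline_cv = list(volume = 0.05, a = 0.08, b = 0.05,
                                             ctHbO2 = 0.10, ctHHb = 0.10),
                          subject_sd = 0.15,
                          day_noise_sd = c(a = 2, b = 2, ctHbO2 = 4,
                                           ctHHb = 5, volume = 8),
                          caliper_cv = 0.02,
                          aspect_mean = 1.2, aspect_sd = 0.05,
                          background = list(a = 1.0, b = 1.3,
                                            ctHbO2 = 30, ctHHb = 15),
                          trajectories = default_trajectories(),
                          instrument = instrument_model(),
                          seed = 1L) {
  stopifnot(all(n_per_group >= 1), 0 %in% days, subject_sd >= 0,
            all(day_noise_sd >= 0), caliper_cv >= 0)
  structure(list(
    n_per_group = n_per_group, days = sort(unique(days)),
    baseline = baseline, baseline_cv = baseline_cv,
    subject_sd = subject_sd, day_noise_sd = day_noise_sd,
    caliper_cv = caliper_cv, aspect_mean = aspect_mean,
    aspect_sd = aspect_sd, background = background,
    trajectories = trajectories,
    phantom_props = calibration_phantom_props(),
    reference_props = reference_phantom_props(),
    control_last_day = 12, treated_early_day = 12,
    instrument = instrument, seed = as.integer(seed)
  ), class = "cohort_config")
}

.interp_anchor <- function(anchors, day) {
  stats::approx(anchors$day, anchors$pct, xout = day, rule = 2)$y
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws per-subject baselines and trajectory multipliers, builds the
#' noiseless ground-truth table (subject multiplier times the group-mean
#' anchor curve), then for every subject-day renders a tumor scene and
#' simulates the raw phase-shifted image stack (with session gain drift
#' relative to that day's calibration measurement) plus a noisy caliper
#' record. One calibration-phantom acquisition is simulated per
#' measurement day.
#'
#' All randomness flows from `config$seed`, so identical configs give
#' identical cohorts.
#'
#' @param config a [cohort_config()]
#' @param ext extinction table (defaults to the packaged one)
#' @param render when `FALSE`, skip scene construction and image synthesis
#'   and generate only the trajectory/caliper level of the cohort (useful
#'   for statistical simulation studies where the imaging chain is not
#'   under test; the `truth` table and caliper records are identical to a
#'   rendered run with the same seed)
#' @return list of class `sfdi_cohort` with `subjects`, `truth` (noiseless
#'   percent-change table plus realized day-level values), `records` (per
#'   subject-day raw stack, scene geometry and caliper record) and
#'   `calibrations` (per-day phantom stacks)
#' @export
generate_cohort <- function(config, ext = load_extinction_table(),
                            render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  inst <- config$instrument
  groups <- rep(names(config$n_per_group), config$n_per_group)
  ids <- unlist(lapply(names(config$n_per_group), function(g) {
    sprintf("%s_%02d", gsub("[^A-Za-z]", "", g), seq_len(config$n_per_group[[g]]))
  }))
  n_sub <- length(ids)
  bm_names <- c("a", "b", "ctHbO2", "ctHHb", "volume")

  ## subject-level draws
  base <- sapply(bm_names, function(v) {
    config$baseline[[v]] * exp(stats::rnorm(n_sub, 0, config$baseline_cv[[v]]))
  })
  mult <- sapply(bm_names, function(v) {
    pmin(pmax(stats::rnorm(n_sub, 1, config$subject_sd), 0.4), 1.6)
  })
  aspect <- pmax(1, stats::rnorm(n_sub, config$aspect_mean, config$aspect_sd))

  ## dropout: Controls all by day 12; about half of each treated arm at
  ## day 12, the remainder at day 30
  last_day <- numeric(n_sub)
  for (g in names(config$n_per_group)) {
    gi <- which(groups == g)
    if (g == "Control") {
      last_day[gi] <- config$control_last_day
    } else {
      n_early <- floor(length(gi) / 2)
      early <- sample(gi, n_early)
      last_day[gi] <- max(config$days)
      last_day[early] <- config$treated_early_day
    }
  }

  subjects <- data.frame(subject = ids, group = groups, dropout_day = last_day,
                         aspect = aspect)
  for (v in bm_names) {
    subjects[[paste0("base_", v)]] <- base[, v]
    subjects[[paste0("mult_", v)]] <- mult[, v]
  }

  ## phase 1: realize all trajectory-level randomness (day noise, session
  ## drift, caliper error) so the truth/caliper level of the cohort is
  ## independent of whether images are rendered afterwards
  truth_rows <- list()
  plan <- list()
  for (d in config$days) {
    alive <- which(last_day >= d)
    if (!length(alive)) next
    for (s in alive) {
      true_pct <- vapply(bm_names, function(v) {
        mult[s, v] * .interp_anchor(config$trajectories[[groups[s]]][[v]], d)
      }, numeric(1))
      meas_pct <- true_pct + stats::rnorm(length(bm_names)) *
        config$day_noise_sd[bm_names]
      names(meas_pct) <- bm_names
      vals <- pmax(base[s, ] * (1 + meas_pct / 100),
                   c(a = 0.3, b = 0.05, ctHbO2 = 1, ctHHb = 1, volume = 10))
      drift <- exp(stats::rnorm(1, 0, inst$drift_sd))
      lw <- (6 * vals[["volume"]] / 3.14)^(2 / 3)
      L <- sqrt(lw * aspect[s]) * exp(stats::rnorm(1, 0, config$caliper_cv))
      W <- sqrt(lw / aspect[s]) * exp(stats::rnorm(1, 0, config$caliper_cv))
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject = ids[s], group = groups[s], day = d,
        t(stats::setNames(true_pct, paste0("true_pct_", bm_names))),
        t(stats::setNames(vals[bm_names], paste0("val_", bm_names))))
      plan[[length(plan) + 1]] <- list(
        subject = ids[s], group = groups[s], day = d, vals = vals,
        drift = drift, caliper = list(L = max(L, W), W = min(L, W)))
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  ## phase 2: render the raw image stacks
  records <- list()
  calibrations <- list()
  if (render) {
    cal_scene <- make_phantom_scene(config$phantom_props, inst)
    for (d in unique(vapply(plan, `[[`, numeric(1), "day"))) {
      calibrations[[as.character(d)]] <- simulate_raw_images(
        cal_scene, inst, drift_gain = 1,
        meta = list(role = "calibration", day = d))
    }
    records <- lapply(plan, function(pl) {
      vals <- pl$vals
      scene <- make_tumor_scene(
        biomarkers = as.list(vals[c("a", "b", "ctHbO2", "ctHHb")]),
        volume_mm3 = vals[["volume"]],
        background = config$background,
        phantom_props = config$phantom_props,
        instrument = inst, ext = ext)
      raw <- simulate_raw_images(scene, inst, drift_gain = pl$drift,
                                 meta = list(subject = pl$subject, day = pl$day))
      list(subject = pl$subject, group = pl$group, day = pl$day, raw = raw,
           caliper = pl$caliper,
           geometry = list(height_mm = scene$height_mm,
                           angle_deg = scene$angle_deg,
                           tumor_mask = scene$tumor_mask,
                           inframe_mask = scene$inframe_mask))
    })
  } else {
    records <- lapply(plan, function(pl) {
      list(subject = pl$subject, group = pl$group, day = pl$day, raw = NULL,
           caliper = pl$caliper, geometry = NULL)
    })
  }
  structure(list(config = config, subjects = subjects, truth = truth,
                 records = records, calibrations = calibrations),
            class = "sfdi_cohort")
}

#' Cohort table from the generator's realized trajectories
#'
#' Builds the same long-format percent-change table as [process_cohort()]
#' but directly from the generator's realized day-level biomarker values,
#' bypassing the imaging chain. Useful for statistical simulation studies
#' (power of contrasts, classifier behavior) where the imaging chain is
#' not the component under test; the imaging chain adds only small
#' recovery error on top of these values.
#'
#' @param cohort an `sfdi_cohort` (rendered or not)
#' @return a `cohort_table`
#' @export
truth_cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "sfdi_cohort"))
  tr <- cohort$truth
  tr$val_ctTHb <- tr$val_ctHbO2 + tr$val_ctHHb
  tr$val_StO2 <- tr$val_ctHbO2 / tr$val_ctTHb
  vars <- c("a", "b", "ctHbO2", "ctHHb", "ctTHb", "StO2", "volume")
  out <- NULL
  for (s in unique(tr$subject)) {
    st <- tr[tr$subject == s, , drop = FALSE]
    st <- st[order(st$day), , drop = FALSE]
    ok <- TRUE
    for (v in vars) {
      pc <- percent_change(st[[paste0("val_", v)]], st$day)
      if (is.null(pc)) { ok <- FALSE; break }
      st[[paste0("pct_change_", v)]] <- pc
    }
    if (ok) out <- rbind(out, st)
  }
  assemble_cohort_table(out)
}
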