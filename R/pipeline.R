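#' Build the per-wavelength lookup tables for a configuration
#'
#' @param config a [cohort_config()] (supplies wavelengths, frequency pair
#'   and refractive index)
#' @param ... passed to [build_lut()] (grid ranges/sizes)
#' @return named list of `sfdi_lut` keyed by wavelength
#' @export
build_luts <- function(config, ...) {
  inst <- config$instrument
  luts <- lapply(inst$wavelengths, function(w) {
    build_lut(w, fx_pair = inst$fx, n_rel = inst$n_rel, ...)
  })
  names(luts) <- as.character(inst$wavelengths)
  luts
}

## Expected in-frame phantom reflectance at calibration-time gain: the
## session drift reference (the in-frame patch is the same material as the
## day's calibration phantom, so its no-drift Rd is the model value).
.session_reference_rd <- function(props, wavelengths, fx_ac, n_rel) {
  t(vapply(wavelengths, function(w) {
    i <- match(w, props$wavelength)
    c(.rd_diffusion(props$mua[i], props$musp[i], 0, n_rel),
      .rd_diffusion(props$mua[i], props$musp[i], fx_ac, n_rel))
  }, numeric(2)))
}

#' Process one subject-day record to ROI biomarker means
#'
#' Runs the full per-acquisition chain: three-phase demodulation,
#' calibration against the day's phantom measurement, in-frame drift
#' correction, surface height/angle correction with the 40-degree mask,
#' two-frequency LUT inversion, per-pixel spectral biomarker fitting, and
#' the artifact-filtered ROI mean over the eroded tumor footprint.
#'
#' @param record one element of `cohort$records`
#' @param calibration_demod demodulated calibration-phantom stack for the
#'   record's day
#' @param config the cohort's [cohort_config()]
#' @param luts lookup tables from [build_luts()]
#' @param ext extinction table
#' @return named list of ROI biomarker means plus `n_valid_pixels`
#' @export
process_subject_day <- function(record, calibration_demod, config, luts, ext) {
  inst <- config$instrument
  dem <- demodulate(record$raw)
  rd <- calibrate(dem, calibration_demod, config$phantom_props, inst$n_rel)
  ref <- .session_reference_rd(config$phantom_props, inst$wavelengths,
                               dem$fx_ac, inst$n_rel)
  rd <- drift_correct(rd, record$geometry$inframe_mask, ref)
  rd <- surface_correct(rd, record$geometry$height_mm,
                        record$geometry$angle_deg, inst$height_gain_per_mm)
  props <- invert_maps(rd, luts)
  bm <- fit_biomarker_maps(props, ext)
  roi <- erode_mask(record$geometry$tumor_mask)
  i659 <- which.min(abs(inst$wavelengths - 659))
  roi_mean(bm, roi, mua_filter_map = props$mua[, , i659])
}

#' Process a simulated cohort into the long-format table
#'
#' Applies [process_subject_day()] to every record, computes caliper tumor
#' volumes, normalizes every biomarker to its day-0 baseline as a percent
#' change, and assembles the validated cohort table. Subjects without a
#' usable day-0 baseline are excluded with a message.
#'
#' @param cohort an `sfdi_cohort` from [generate_cohort()]
#' @param luts lookup tables (built from the config when omitted)
#' @param ext extinction table
#' @param calibration_blur half-width of the spatial box blur applied to
#'   each day's calibration-phantom maps (see [smooth_calibration()]); the
#'   phantom is homogeneous, so this removes single-acquisition noise that
#'   would otherwise propagate to every subject measured that day
#' @return a `cohort_table` data.frame: one row per subject-day with
#'   `pct_change_*` and raw `raw_*` columns and `n_valid_pixels`
#' @export
process_cohort <- function(cohort, luts = NULL, ext = load_extinction_table(),
                           calibration_blur = 2) {
  stopifnot(inherits(cohort, "sfdi_cohort"))
  config <- cohort$config
  if (is.null(luts)) luts <- build_luts(config)
  cal_demod <- lapply(cohort$calibrations, function(r)
    smooth_calibration(demodulate(r), calibration_blur))

  vars <- c("a", "b", "ctHbO2", "ctHHb", "ctTHb", "StO2")
  rows <- lapply(cohort$records, function(rec) {
    m <- process_subject_day(rec, cal_demod[[as.character(rec$day)]],
                             config, luts, ext)
    vol <- tumor_volume(rec$caliper$L, rec$caliper$W)
    data.frame(subject = rec$subject, group = rec$group, day = rec$day,
               t(stats::setNames(unlist(m[vars]), paste0("raw_", vars))),
               raw_volume = vol, n_valid_pixels = m$n_valid_pixels)
  })
  tab <- do.call(rbind, rows)

  out <- NULL
  for (s in unique(tab$subject)) {
    st <- tab[tab$subject == s, , drop = FALSE]
    st <- st[order(st$day), , drop = FALSE]
    ok <- TRUE
    for (v in c(vars, "volume")) {
      pc <- percent_change(st[[paste0("raw_", v)]], st$day)
      if (is.null(pc)) { ok <- FALSE; break }
      st[[paste0("pct_change_", v)]] <- pc
    }
    if (ok) out <- rbind(out, st)
  }
  assemble_cohort_table(out)
}

#' End-to-end longitudinal and discriminant analysis of a cohort table
#'
#' Fits the short-term (all three arms through Day 12) and long-term (CPA
#' vs CPA+Ab through Day 30) GEE models for the outcomes of interest, the
#' per-day post-hoc group contrasts at both significance thresholds, and
#' the short- and long-term leave-one-out LDA accuracy grids.
#'
#' @param table a `cohort_table`
#' @param outcomes outcome biomarkers for the GEE models
#' @return list with `gee` (per scope, per outcome), `contrasts`, and
#'   `grids` (`short`, `long`)
#' @export
run_cohort_analysis <- function(table,
                                outcomes = c("a", "ctHHb", "volume")) {
  if (is.null(table) || nrow(table) == 0) stop("empty cohort table")
  gee <- list(); contrasts <- list()
  for (scope in c("short", "long")) {
    gee[[scope]] <- list(); contrasts[[scope]] <- list()
    for (oc in outcomes) {
      fit <- fit_gee(table, oc, scope)
      gee[[scope]][[oc]] <- fit
      contrasts[[scope]][[oc]] <- posthoc_contrasts(fit)
    }
  }
  grids <- list(short = accuracy_grid(table, scope = "short"),
                long = accuracy_grid(table, scope = "long"))
  list(gee = gee, contrasts = contrasts, grids = grids)
}

#' Write / read a raw stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered wavelength-outer, frequency-middle, phase-inner; the
#' sidecar records wavelengths, frequencies, phases, pixel pitch and
#' acquisition metadata. Frames are stored as 32-bit float TIFF.
#'
#' @param raw an `sfdi_raw`
#' @param path TIFF path (sidecar gets `.json` appended)
#' @export
write_raw_tiff <- function(raw, path) {
  stopifnot(inherits(raw, "sfdi_raw"))
  pages <- list()
  for (k in seq_along(raw$wavelengths))
    for (j in seq_along(raw$fx))
      for (p in 1:3)
        pages[[length(pages) + 1]] <- raw$frames[, , k, j, p]
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(wavelengths = raw$wavelengths, fx = raw$fx,
               phases = raw$phases, pixel_pitch_mm = raw$pixel_pitch_mm,
               meta = raw$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_raw_tiff
#' @export
read_raw_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- nrow(pages[[1]])
  n_wl <- length(meta$wavelengths); n_fx <- length(meta$fx)
  frames <- array(NA_real_, c(n, n, n_wl, n_fx, 3))
  q <- 1
  for (k in seq_len(n_wl))
    for (j in seq_len(n_fx))
      for (p in 1:3) {
        frames[, , k, j, p] <- pages[[q]]
        q <- q + 1
      }
  structure(list(frames = frames, wavelengths = meta$wavelengths,
                 fx = meta$fx, phases = meta$phases,
                 pixel_pitch_mm = meta$pixel_pitch_mm,
                 meta = as.list(meta$meta)),
            class = "sfdi_raw")
}

#' Write cohort ground truth and caliper records as CSV
#'
#' @param cohort an `sfdi_cohort`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  cal <- do.call(rbind, lapply(cohort$records, function(r) {
    data.frame(subject = r$subject, group = r$group, day = r$day,
               L_mm = r$caliper$L, W_mm = r$caliper$W)
  }))
  cal_path <- file.path(dir, "caliper.csv")
  utils::write.csv(cal, cal_path, row.names = FALSE)
  invisible(c(truth_path, cal_path))
}

#' Write / read a cohort configuration as YAML
#'
#' Serializes the scalar and tabular parts of a [cohort_config()] (group
#' sizes, schedule, baselines, noise model, trajectory anchors, phantom
#' properties, instrument scalars, seed). The instrument gain map is
#' regenerated from the instrument constructor on read.
#'
#' @param config a [cohort_config()]
#' @param path YAML file path
#' @export
write_cohort_config <- function(config, path) {
  inst <- config$instrument
  obj <- list(
    n_per_group = as.list(config$n_per_group),
    days = config$days,
    baseline = config$baseline,
    baseline_cv = config$baseline_cv,
    subject_sd = config$subject_sd,
    day_noise_sd = as.list(config$day_noise_sd),
    caliper_cv = config$caliper_cv,
    aspect_mean = config$aspect_mean,
    aspect_sd = config$aspect_sd,
    background = config$background,
    trajectories = lapply(config$trajectories, function(g)
      lapply(g, function(df) list(day = df$day, pct = df$pct))),
    instrument = list(n_px = inst$n_px, pixel_pitch_mm = inst$pixel_pitch_mm,
                      wavelengths = inst$wavelengths, fx = inst$fx,
                      phases = inst$phases, mtf_ac = inst$mtf_ac,
                      noise_frac = inst$noise_frac, drift_sd = inst$drift_sd,
                      height_gain_per_mm = inst$height_gain_per_mm,
                      n_rel = inst$n_rel),
    seed = config$seed)
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  obj <- yaml::read_yaml(path)
  traj <- lapply(obj$trajectories, function(g)
    lapply(g, function(x) data.frame(day = x$day, pct = x$pct)))
  inst <- do.call(instrument_model, obj$instrument)
  cohort_config(
    n_per_group = unlist(obj$n_per_group),
    days = obj$days, baseline = obj$baseline,
    baseline_cv = obj$baseline_cv, subject_sd = obj$subject_sd,
    day_noise_sd = unlist(obj$day_noise_sd), caliper_cv = obj$caliper_cv,
    aspect_mean = obj$aspect_mean, aspect_sd = obj$aspect_sd,
    background = obj$background, trajectories = traj,
    instrument = inst, seed = obj$seed)
}
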