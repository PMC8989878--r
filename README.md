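# sfdiresponse

Simulation and analysis pipeline for **spatial frequency domain imaging
(SFDI)** monitoring of tumor treatment response in a paired
responsive/resistant murine breast-cancer design.

SFDI projects sinusoidal illumination patterns at two spatial frequencies
(0 and 0.1 mm⁻¹, three phase offsets, four NIR wavelengths:
659/691/731/851 nm) and demodulates the remitted light to separate tissue
absorption (μa) from reduced scattering (μ′s) per pixel. Scattering is
summarized by the power law μ′s(λ) = a·(λ/800)⁻ᵇ — amplitude *a* is the
headline prognostic biomarker — and absorption is unmixed by Beer's law
into oxy-/deoxy-hemoglobin (ctHbO₂, ctHHb) with composites ctTHb and
StO₂. The emulated study follows three arms (untreated Control n=3;
metronomic cyclophosphamide, CPA, n=9, treatment-responsive; CPA +
IFNAR-1 antibody, CPA+Ab, n=14, treatment-resistant) from Day 0 to
Day 30, asking whether early changes in optical scattering discriminate
responders from resistant tumors before tumor volume can.

The package provides, as tested library code:

- a synthetic-data generator (raw phase-shifted image stacks, caliper
  records, ground truth) whose defaults are the study conditions;
- the processing chain: three-phase demodulation, phantom calibration,
  in-frame drift correction, height/angle correction with the 40° mask,
  two-frequency lookup-table inversion, per-pixel spectral biomarker
  fits, artifact-filtered ROI means, percent change from baseline;
- the statistics: GEE longitudinal models (normal/identity, AR(1) working
  correlation, cluster-robust SEs) with per-day post-hoc contrasts, and
  leave-one-out cross-validated LDA accuracy grids over feature sets ×
  days.

The numbered scripts under `analysis/` run the study end to end and write
tables and figures under `results/`.

## Worked example

```r
library(sfdiresponse)

cfg    <- cohort_config(seed = 1)   # 26 subjects, Days 0-30, default noise
cohort <- generate_cohort(cfg)      # raw stacks + calipers + ground truth
tab    <- process_cohort(cohort)    # full imaging chain -> long-format table

fit <- fit_gee(tab, "a", "short")   # % change in scattering amplitude
gee_adjusted_means(fit,
  data.frame(day_f = factor(5, levels = fit$xlevels$day_f),
             group_f = factor(c("Control", "CPA", "CPA+Ab"),
                              levels = fit$xlevels$group_f)))
#>   day_f group_f   estimate        se
#> 1     5 Control -10.153436 0.7752490
#> 2     5     CPA   7.592226 0.8782279
#> 3     5  CPA+Ab  -9.620189 0.7262316
```

By Day 5 the responsive arm's scattering amplitude has risen about +9%
while both the resistant and control arms have fallen about −10% — the
arms separate optically while their tumor volumes still overlap. The
discriminant grids make the same point as classification accuracy:

```r
g_short <- accuracy_grid(tab, scope = "short")  # 3 arms, Days 1-6
g_long  <- accuracy_grid(tab, scope = "long")   # CPA vs CPA+Ab
g_short["ctHHb+a", "5"]   #> 1.00  two optical features, three groups, Day 5
g_long["a", "4"]          #> 1.00  scattering alone, Day 4
g_long["volume", "4"]     #> 0.26  volume alone is near/below chance at Day 4
```

Run the whole workflow:

```sh
Rscript analysis/01_phantom_validation.R   # phantom round trip, all 4 wavelengths
Rscript analysis/02_simulate_cohort.R      # cohort + raw TIFF stacks on disk
Rscript analysis/03_process_images.R       # images -> results/cohort_table.csv
Rscript analysis/04_longitudinal_gee.R     # GEE fits + per-day contrasts
Rscript analysis/05_classification.R       # LOOCV accuracy grids + heatmaps
```

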