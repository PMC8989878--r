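#!/usr/bin/env Rscript
## Simulate the default three-arm longitudinal cohort (Control n=3, CPA
## n=9, CPA+Ab n=14; Days 0-6 daily then every 3 days to Day 30, with the
## euthanasia schedule) and write its ground truth, caliper records, and a
## sample of raw image stacks to disk.

suppressPackageStartupMessages(library(sfdiresponse))
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(seed = 1)
write_cohort_config(cfg, "results/cohort/config.yaml")
cohort <- generate_cohort(cfg)

write_cohort_csv(cohort, "results/cohort")
message("Cohort: ", nrow(cohort$subjects), " subjects, ",
        length(cohort$records), " subject-day acquisitions, ",
        length(cohort$calibrations), " daily calibration measurements.")
print(table(cohort$subjects$group, cohort$subjects$dropout_day,
            dnn = c("arm", "last day")))

## raw stacks for one subject's first days, in the on-disk TIFF format
demo <- Filter(function(r) r$subject == "CPA_01" & r$day <= 2, cohort$records)
for (r in demo) {
  write_raw_tiff(r$raw, sprintf("results/cohort/%s_day%02d.tif", r$subject, r$day))
}
message("Wrote ", length(demo), " raw stacks (multi-page TIFF + JSON sidecar) ",
        "for subject CPA_01 under results/cohort/.")

dir.create("scratch", showWarnings = FALSE)
saveRDS(cohort, "scratch/cohort.rds")  # local handoff to 03; not a deliverable
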