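#!/usr/bin/env Rscript
## Early-timepoint classification: leave-one-out cross-validated LDA over
## feature sets x days. Short-term grid: all three arms, Days 1-6.
## Long-term grid: responsive (CPA) vs resistant (CPA+Ab), all days to 30.
## Renders the two grids as heatmaps.

suppressPackageStartupMessages({
  library(sfdiresponse)
  library(ggplot2)
})
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
tab <- read.csv("results/cohort_table.csv")
class(tab) <- c("cohort_table", "data.frame")

plot_grid <- function(g, title, path) {
  df <- as.data.frame(as.table(unclass(g)))
  names(df) <- c("features", "day", "accuracy")
  df$day <- factor(df$day, levels = colnames(g))
  p <- ggplot(df, aes(day, features, fill = accuracy)) +
    geom_tile(color = "white") +
    geom_text(aes(label = ifelse(is.na(accuracy), "",
                                 sprintf("%.2f", accuracy))), size = 3) +
    scale_fill_gradient(low = "#fff5eb", high = "#d94801",
                        limits = c(0, 1), na.value = "grey90") +
    labs(title = title, x = "treatment day", y = NULL) +
    theme_minimal(base_size = 11)
  ggsave(path, p, width = 7.5, height = 3.2, dpi = 150)
}

g_short <- accuracy_grid(tab, scope = "short")
g_long <- accuracy_grid(tab, scope = "long")
write.csv(as.data.frame(unclass(g_short)), "results/accuracy_grid_short.csv")
write.csv(as.data.frame(unclass(g_long)), "results/accuracy_grid_long.csv")
plot_grid(g_short, "Short-term LOOCV accuracy (3 arms, Days 1-6)",
          "results/figures/accuracy_grid_short.png")
plot_grid(g_long, "Long-term LOOCV accuracy (CPA vs CPA+Ab)",
          "results/figures/accuracy_grid_long.png")

message("Short-term grid (3 arms):")
print(round(unclass(g_short), 2))
message("Long-term grid, first six days (CPA vs CPA+Ab):")
print(round(unclass(g_long)[, 1:6], 2))
message("The two-feature set (ctHHb + a) reaches ",
        sprintf("%.2f", g_short["ctHHb+a", "5"]),
        " accuracy for the three-group problem on Day 5; scattering alone ",
        "separates responsive from resistant with ",
        sprintf("%.2f", g_long["a", "4"]), " accuracy on Day 4, while ",
        "tumor volume is still near chance (",
        sprintf("%.2f", g_long["volume", "4"]), ").")
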