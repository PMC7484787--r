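#!/usr/bin/env Rscript
# Stage 6 — population statistics.
#
# Kolmogorov-Smirnov comparisons of every decay parameter between
# resting and activated mast cells (in vitro and in vivo), plus the 2-D
# segmentation scatter tables used to separate cell types.

suppressPackageStartupMessages(library(tpeflim))
co <- read_cohort("results/cohort.csv")
params <- c("tau1", "tau2", "tau_m", "ratio", "intensity")

cmp <- do.call(rbind, c(
  lapply(params, function(p)
    population_compare(co[co$context == "in_vitro", ], p,
                       "resting_mc", "activated_mc")),
  lapply(params, function(p)
    population_compare(co[co$context == "in_vivo", ], p,
                       "resting_mc", "activated_mc"))))
cmp$context <- rep(c("in_vitro", "in_vivo"), each = length(params))
write.csv(cmp, "results/population_comparisons.csv", row.names = FALSE)
print(cmp[, c("context", "parameter", "mean_a", "mean_b", "D", "p",
              "significant")], digits = 3)
cat(sprintf("%d of %d comparisons significant at p < 0.05 (uncorrected)\n",
            sum(cmp$significant), nrow(cmp)))

for (pair in c("tau1-tau2", "tau1-ratio", "tau2-ratio", "tau2-asym")) {
  sc <- segmentation_scatter(co, pair)
  write.csv(sc$points, sprintf("results/scatter_%s.csv",
                               gsub("-", "_", pair)), row.names = FALSE)
}
cat("Segmentation scatter tables written.\n")
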