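#!/usr/bin/env Rscript
# Stage 4 — bright-spot detection and the mast-cell search cascade.
#
# Detects bright fluorescent spots on the binned intensity map of the
# demo scene, measures each candidate (size, circularity, per-cell decay
# parameters) and applies the rule cascade: depth > 70 um, ~10 um size,
# fibroblast exclusion at 20 um, then the tau_m gates (> 1,000 ps
# resting, < 800 ps activated).

suppressPackageStartupMessages(library(tpeflim))
cube <- read_cube("results/demo_scene.tif")
fits <- read.csv("results/fit_maps.csv")

totals <- apply(bin_decays(cube, 3)$counts, c(1, 2), sum)
masks <- detect_bright_spots(totals / cube$power, cube$pixel_pitch)
cat(sprintf("%d candidate bright spots\n", length(masks)))

n <- dim(cube$counts)[1]
fields <- c("a1", "a2", "tau1", "tau2", "tau_m", "ratio", "asym", "chi2",
            "intensity")
fm <- structure(list(
  maps = setNames(lapply(fields, function(f) matrix(fits[[f]], n, n)),
                  fields),
  valid = matrix(fits$valid, n, n),
  pixel_pitch = cube$pixel_pitch, power = cube$power,
  channel_width = cube$channel_width), class = "fit_maps")

rows <- lapply(seq_along(masks), function(i) {
  r <- measure_cell(masks[[i]], fm, cube)
  data.frame(candidate = i, diameter_um = r$equivalent_diameter,
             circularity = r$circularity, shape = r$shape_flag,
             intensity = r$mean_intensity, tau_m = r$fit_summary$tau_m,
             ratio = r$fit_summary$ratio, label = mc_search(r))
})
cells <- do.call(rbind, rows)
write.csv(cells, "results/detected_cells.csv", row.names = FALSE)
print(cells, digits = 3)

# detection at 4 MAD finds the bright activated cell but can miss the
# dim resting population (300 vs ~250 photons/mW background) — the same
# under-detection expected in vivo. The cascade itself is checked on the
# ground-truth masks:
truth <- read.csv("results/demo_scene_truth.csv")
gt <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
  ctr <- c(truth$center_y_um[i], truth$center_x_um[i]) / cube$pixel_pitch
  r <- sqrt(truth$area_px[i] / pi)
  yy <- matrix(seq_len(n), n, n)
  mask <- (yy - ctr[1])^2 + (t(yy) - ctr[2])^2 <= r^2
  rec <- measure_cell(mask, fm, cube)
  data.frame(class = truth$class[i], true_tau_m = with(truth[i, ],
             (ratio * tau1 + tau2) / (ratio + 1)),
             measured_tau_m = rec$fit_summary$tau_m,
             label = mc_search(rec))
}))
cat("\nGround-truth masks through the cascade:\n")
print(gt, digits = 4)
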