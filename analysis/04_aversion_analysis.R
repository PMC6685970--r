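#!/usr/bin/env Rscript
# Aversion analysis of the simulated trials: normalized distance to the odor
# source, near-third occupancy in the first-1-min and full-10-min windows,
# aversion indices against the water controls, raster and positional
# heat-map data.

suppressPackageStartupMessages(library(olfmap))

src <- "results/behavior"
out <- "results/aversion"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
trials <- read.csv(file.path(src, "trial_manifest.csv"))

cage <- c(200, 318); source_pt <- c(100, 0)
far <- cage[2] - source_pt[2]

occ <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
  tr <- read_track_csv(file.path(src, paste0(trials$trial[i], "_track.csv")))
  tr <- normalize_distance(tr, source_pt, far)
  data.frame(trial = trials$trial[i], type = trials$type[i],
             beta = trials$beta[i],
             occ_1min = occupancy(tr, 1 / 3, window = c(0, 60)),
             occ_10min = occupancy(tr, 1 / 3),
             occ_far_10min = occupancy(tr, 1 / 3, far = TRUE))
}))
write.csv(occ, file.path(out, "occupancy.csv"), row.names = FALSE)

controls_10 <- occ$occ_10min[occ$type == "DW"]
controls_1 <- occ$occ_1min[occ$type == "DW"]
idx <- do.call(rbind, lapply(which(occ$type == "odor"), function(i) {
  r10 <- aversion_index(occ$occ_10min[i], controls_10, "full_10min")
  r1 <- aversion_index(occ$occ_1min[i], controls_1, "first_1min")
  data.frame(trial = occ$trial[i], beta = occ$beta[i],
             index_1min = r1$index, index_10min = r10$index)
}))
write.csv(idx, file.path(out, "aversion_indices.csv"), row.names = FALSE)
cat("mean aversion index (10 min) by beta:\n")
print(aggregate(index_10min ~ beta, idx, mean))

# raster + positional heat map for the first trial of each type
for (tname in c(occ$trial[match(c("DW", "odor"), occ$type)])) {
  tr <- read_track_csv(file.path(src, paste0(tname, "_track.csv")))
  tr <- normalize_distance(tr, source_pt, far)
  write.csv(raster_data(tr), file.path(out, paste0(tname, "_raster.csv")),
            row.names = FALSE)
  hm <- position_heatmap(tr, bins = c(20, 32),
                         range_x = c(0, cage[1]), range_y = c(0, cage[2]))
  write.csv(as.data.frame(as.table(hm)),
            file.path(out, paste0(tname, "_heatmap.csv")), row.names = FALSE)
}

write_manifest(file.path(out, "manifest.json"),
               list(region = "dhat < 1/3", windows = c("0-60 s", "0-600 s"),
                    source = source_pt, far_distance = far), seed = NA)
cat("aversion analysis ->", out, "\n")
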