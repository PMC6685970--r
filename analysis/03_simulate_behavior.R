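#!/usr/bin/env Rscript
# Simulate the innate-aversion assay: water-control trials (no drift) and
# odor trials across avoidance strengths. Ground-truth tracks go to CSV;
# one odor trial is also rendered to a short demonstration TIFF clip.

suppressPackageStartupMessages(library(olfmap))

seed <- 20260919L
out <- "results/behavior"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

trials <- rbind(
  data.frame(trial = paste0("DW_",  1:6),  type = "DW",   beta = 0),
  data.frame(trial = paste0("odor_weak_",   1:4), type = "odor", beta = 0.5),
  data.frame(trial = paste0("odor_strong_", 1:4), type = "odor", beta = 2)
)

for (i in seq_len(nrow(trials))) {
  spec <- behavior_spec(beta = trials$beta[i], seed = seed + i)
  tr <- gen_trajectory(spec)
  write.csv(tr$track[, c("t", "x", "y", "valid")],
            file.path(out, paste0(trials$trial[i], "_track.csv")),
            row.names = FALSE)
}
write.csv(trials, file.path(out, "trial_manifest.csv"), row.names = FALSE)

# a 20-s rendered clip of one strong-avoidance trial (full videos are
# rendered lazily in memory by the analysis, never stored)
spec <- behavior_spec(duration = 20, beta = 2, seed = seed + 99L)
tr <- gen_trajectory(spec)
clip <- lapply(seq(1, tr$n_frames, by = 5), tr$render_frame)
write_tiff_stack(clip, file.path(out, "demo_clip.tif"))

write_manifest(file.path(out, "manifest.json"),
               list(n_trials = nrow(trials), duration = 600, fps = 25,
                    cage = c(200, 318), sigma = 2.5, lambda_odor = 30), seed)
cat(sprintf("simulated %d trials -> %s\n", nrow(trials), out))
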