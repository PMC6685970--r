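#!/usr/bin/env Rscript
# Simulate a set of coronal olfactory-bulb sections with labeled nuclei and
# exact ground truth. Writes a TIFF stack plus ground-truth CSV/JSON sidecars
# under results/sections/.

suppressPackageStartupMessages(library(olfmap))

seed <- 20260919L
out <- "results/sections"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# six sections anterior -> posterior; the bulb narrows posteriorly, the
# dorsal activity density is higher than ventral (an aversive-odor-like map)
n_sections <- 6
axes <- cbind(a = seq(380, 300, length.out = n_sections),
              b = seq(300, 240, length.out = n_sections))
lambda_dorsal <- function(theta) 6 + 14 * exp(-((theta %% (2 * pi)) - 3 * pi / 2)^2 / 0.6)

sections <- lapply(seq_len(n_sections), function(i) {
  gen_section(section_spec(a = axes[i, "a"], b = axes[i, "b"],
                           lambda = lambda_dorsal, size = c(920, 760),
                           min_sep = 10, seed = seed + i))
})

write_tiff_stack(lapply(sections, `[[`, "image"), file.path(out, "sections.tif"))
truth <- do.call(rbind, lapply(seq_along(sections), function(i) {
  cbind(section = i, sections[[i]]$nuclei)
}))
write.csv(truth, file.path(out, "nuclei_truth.csv"), row.names = FALSE)
refs <- do.call(rbind, lapply(seq_along(sections), function(i) {
  data.frame(section = i,
             ventral_x = sections[[i]]$refs$ventral[1],
             ventral_y = sections[[i]]$refs$ventral[2],
             dorsal_x = sections[[i]]$refs$dorsal_medial[1],
             dorsal_y = sections[[i]]$refs$dorsal_medial[2],
             ocam_lo = sections[[i]]$ocam$lo,
             ocam_hi = sections[[i]]$ocam$hi)
}))
write.csv(refs, file.path(out, "reference_points.csv"), row.names = FALSE)
write_manifest(file.path(out, "manifest.json"),
               list(n_sections = n_sections, size = c(920, 760),
                    min_sep = 10, lambda = "dorsal-peaked"), seed)

cat(sprintf("simulated %d sections, %d nuclei total -> %s\n",
            n_sections, nrow(truth), out))
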