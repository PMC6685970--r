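#!/usr/bin/env Rscript
# Reconstruct the unrolled odor map from the simulated sections: trace each
# glomerular-layer centerline, straighten, assemble anterior -> posterior,
# detect labeled cells, bin into 100-um columns, classify the OCAM-negative
# dorsal region, and render the clipped rainbow heat map.

suppressPackageStartupMessages(library(olfmap))

src <- "results/sections"
out <- "results/odor_map"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
stopifnot(file.exists(file.path(src, "sections.tif")))

imgs <- read_tiff_stack(file.path(src, "sections.tif"))
refs <- read.csv(file.path(src, "reference_points.csv"))
truth <- read.csv(file.path(src, "nuclei_truth.csv"))

sheets <- list(); particles <- list()
for (i in seq_along(imgs)) {
  path <- trace_centerline(imgs[[i]], scale = 1,
                           ref_ventral = c(refs$ventral_x[i], refs$ventral_y[i]),
                           ref_dorsal = c(refs$dorsal_x[i], refs$dorsal_y[i]),
                           section_id = paste("section", i))
  sheets[[i]] <- straighten(imgs[[i]], path, half_width = 20)
  particles[[i]] <- detect_cells(sheets[[i]], size_range = c(10, 60),
                                 sheet_index = i)
}
odor_map <- assemble_map(sheets, section_spacing = 80)
pts <- do.call(rbind, particles)
class(pts) <- c("particle_set", "data.frame")

counts <- bin_columns(pts)
write_column_counts(counts, file.path(out, "column_counts.csv"))

region <- data.frame(row = refs$section, lo = refs$ocam_lo, hi = refs$ocam_hi)
hist <- classify_columns(counts, region)
write_histogram_csv(hist, file.path(out, "response_histogram.csv"))
print(hist)

ras <- heatmap_raster(counts, ocam_region = region)
write_heatmap_png(ras, file.path(out, "heatmap.png"))

# fidelity against the generator's ground truth
truth_tab <- aggregate(column ~ section, truth, length)
det_tab <- aggregate(count ~ row, counts, sum)
cmp <- merge(truth_tab, det_tab, by.x = "section", by.y = "row")
names(cmp) <- c("section", "true_cells", "detected_cells")
write.csv(cmp, file.path(out, "recovery_per_section.csv"), row.names = FALSE)
cat(sprintf("detected %d / %d true cells across %d sheets\n",
            sum(cmp$detected_cells), sum(cmp$true_cells), length(imgs)))

write_manifest(file.path(out, "manifest.json"),
               list(half_width = 20, size_range = c(10, 60),
                    column_width = 100, section_spacing = 80,
                    threshold = "auto"), seed = NA)
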