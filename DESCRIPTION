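Package: olfmap
Title: Unrolled Odor Maps and Innate Aversion Analysis for the Mouse
    Olfactory Bulb
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs "unrolled odor maps" of the olfactory-bulb
    glomerular layer from coronal section images (centerline tracing,
    curved-layer straightening, anterior-to-posterior sheet assembly),
    quantifies Egr1-positive cells as size-filtered particles into
    100-micrometre columns with response-class histograms and clipped
    heat-map rasters, analyses innate-aversion behavioral videos
    (binarization, tail-removing blur, body-centroid tracking,
    normalized distance to the odor source, occupancy times and the
    aversion index), and provides the supporting group statistics
    (two-sample t-tests from raw data or summaries, Benjamini-Hochberg
    adjustment, log2 normalization, pseudocount fold changes,
    dorsal-ventral distributions). Includes seeded synthetic-data
    generators for section images, behavioral trajectories and rendered
    frames, and cell-count tables, so the whole pipeline is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
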