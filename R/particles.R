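#' Binarize an image at a fixed or automatic threshold
#'
#' Foreground is strictly greater than the threshold. `NA` pixels (the
#' no-data sentinel used by assembled maps) are always background.
#'
#' @param img numeric matrix.
#' @param threshold numeric threshold, or `"auto"` for the Otsu threshold
#'   computed on the non-sentinel pixels.
#' @return logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(img, threshold = "auto") {
  if (identical(threshold, "auto")) threshold <- auto_threshold(img)
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  mask <- !is.na(img) & img > threshold
  mask
}

#' Remove specks and split touching blobs
#'
#' Connected components smaller than `min_speck_area` pixels are removed
#' (despeckle); remaining touching convex blobs are split by a
#' distance-transform watershed.
#'
#' @param mask logical or 0/1 matrix.
#' @param min_speck_area components with fewer pixels are discarded.
#' @param watershed split touching blobs (default `TRUE`).
#' @param watershed_tolerance minimum depth between two distance-transform
#'   peaks for a split; 0.5 resolves touching nucleus-scale discs without
#'   fragmenting single ones.
#' @return integer label matrix (0 = background).
#' @export
despeckle_and_split <- function(mask, min_speck_area = 4, watershed = TRUE,
                                watershed_tolerance = 0.5) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_speck_area)
  if (length(drop)) m[lab %in% drop] <- 0
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (watershed) {
    d <- EBImage::distmap(m)
    lab <- EBImage::watershed(d, tolerance = watershed_tolerance, ext = 1)
  } else {
    lab <- EBImage::bwlabel(m)
  }
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

#' Size-filtered particle analysis
#'
#' One particle per label whose pixel area lies in `size_range`
#' (inclusive); the centroid is the unweighted area centroid, reported in
#' 0-based pixels and in micrometres.
#'
#' @param labels integer label matrix from [despeckle_and_split()].
#' @param size_range `c(min, max)` area in pixels^2.
#' @param scale micrometres per pixel (for the `x_um`, `y_um` columns).
#' @param sheet index of the source sheet, stored per particle.
#' @return data.frame of class `particle_set`: `x`, `y` (0-based px),
#'   `x_um`, `y_um`, `area` (px^2), `sheet`.
#' @export
count_particles <- function(labels, size_range = c(10, 200), scale = 1,
                            sheet = 1L) {
  if (size_range[1] > size_range[2])
    stop("invalid size filter: size_min > size_max")
  empty <- data.frame(x = numeric(0), y = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), area = numeric(0),
                      sheet = integer(0))
  class(empty) <- c("particle_set", "data.frame")
  if (!any(labels > 0)) return(empty)
  idx <- which(labels > 0, arr.ind = TRUE)
  lv <- labels[labels > 0]
  area <- tabulate(lv)
  sx <- tapply(idx[, 2] - 1, lv, mean)   # 0-based x = col - 1
  sy <- tapply(idx[, 1] - 1, lv, mean)
  keep <- which(area >= size_range[1] & area <= size_range[2])
  keep <- keep[area[keep] > 0]
  if (!length(keep)) return(empty)
  out <- data.frame(x = as.numeric(sx[as.character(keep)]),
                    y = as.numeric(sy[as.character(keep)]),
                    area = area[keep], sheet = as.integer(sheet))
  out$x_um <- out$x * scale
  out$y_um <- out$y * scale
  out <- out[order(out$x), c("x", "y", "x_um", "y_um", "area", "sheet")]
  rownames(out) <- NULL
  class(out) <- c("particle_set", "data.frame")
  out
}

#' Detect labeled cells on one straightened sheet
#'
#' Convenience pipeline: binarize, despeckle + watershed, size-filtered
#' particle analysis, on a single `unrolled_sheet`.
#'
#' @param sheet an `unrolled_sheet` matrix.
#' @param threshold see [binarize()].
#' @param min_speck_area,size_range see [despeckle_and_split()],
#'   [count_particles()].
#' @param sheet_index stored in the particle table.
#' @return a `particle_set` data.frame.
#' @export
detect_cells <- function(sheet, threshold = "auto", min_speck_area = 4,
                         size_range = c(10, 200), sheet_index = 1L) {
  mask <- binarize(sheet, threshold)
  lab <- despeckle_and_split(mask, min_speck_area = min_speck_area)
  count_particles(lab, size_range = size_range,
                  scale = attr(sheet, "scale"), sheet = sheet_index)
}
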