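#' @importFrom stats rnorm rpois runif approx pt sd var
#' @importFrom utils write.csv read.csv
NULL

# Pixel convention used throughout: an image is a numeric matrix m[row, col];
# pixel (row i, col j) has its centre at continuous coordinates
# x = j - 1, y = i - 1 (0-based, x right, y down). Intensities live on a
# nominal 8-bit 0..255 scale.

#' Bilinear interpolation of an image at arbitrary subpixel points
#'
#' Points use the package's 0-based pixel-centre convention. Points outside
#' the image evaluate to `outside` (default 0).
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of 0-based coordinates (x = column direction,
#'   y = row direction).
#' @param outside value returned for points outside the image support.
#' @return numeric vector of interpolated intensities, one per point.
#' @keywords internal
bilinear <- function(img, x, y, outside = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  # clamp index lookups; record which points are genuinely outside
  out <- x < 0 | x > nc - 1 | y < 0 | y > nr - 1
  cx0 <- pmin(pmax(x0, 0), nc - 1); cx1 <- pmin(cx0 + 1, nc - 1)
  cy0 <- pmin(pmax(y0, 0), nr - 1); cy1 <- pmin(cy0 + 1, nr - 1)
  v <- img[cbind(cy0 + 1, cx0 + 1)] * (1 - fx) * (1 - fy) +
       img[cbind(cy0 + 1, cx1 + 1)] * fx       * (1 - fy) +
       img[cbind(cy1 + 1, cx0 + 1)] * (1 - fx) * fy +
       img[cbind(cy1 + 1, cx1 + 1)] * fx       * fy
  v[out] <- outside
  v
}

#' Separable Gaussian blur restricted to the foreground bounding box
#'
#' Equivalent to a full-frame Gaussian convolution for any pixel farther than
#' the padded margin from the crop edge; the crop is padded by `4 * sigma` so
#' blurred mass never leaks across it. Used by the frame preprocessor, where
#' the foreground (a mouse body) occupies a small fraction of the frame.
#'
#' @param mask numeric matrix (typically 0/1).
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred matrix, same dimensions as `mask`.
#' @keywords internal
gauss_blur_bbox <- function(mask, sigma) {
  fg <- which(mask > 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (nrow(fg) == 0L) return(out)
  pad <- ceiling(4 * sigma)
  r0 <- max(1L, min(fg[, 1]) - pad); r1 <- min(nrow(mask), max(fg[, 1]) + pad)
  c0 <- max(1L, min(fg[, 2]) - pad); c1 <- min(ncol(mask), max(fg[, 2]) + pad)
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  k <- function(n) {
    i <- seq_len(n)
    K <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
    K / rowSums(K)
  }
  out[r0:r1, c0:c1] <- k(nrow(sub)) %*% sub %*% t(k(ncol(sub)))
  out
}

#' Otsu automatic threshold
#'
#' Histogram-based between-class-variance maximization on the non-NA pixels.
#' Errors on a constant image (there are no separable classes).
#'
#' @param img numeric matrix; NA pixels (no-data sentinel) are ignored.
#' @param levels number of histogram bins.
#' @return scalar threshold on the image's own intensity scale.
#' @export
auto_threshold <- function(img, levels = 256L) {
  v <- img[!is.na(img)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("auto threshold undefined: image is constant (no separable classes)")
  th <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)),
                      range = rng, levels = levels)
  as.numeric(th)
}

#' Write a run manifest recording every setting that affects results
#'
#' Emitted beside each analysis output so a run can be reproduced exactly.
#' Contains the configuration (with all defaults filled in), the seed, and
#' package/R versions; deliberately no timestamp, so reruns are byte-identical.
#'
#' @param path output JSON path.
#' @param config named list of settings.
#' @param seed integer seed the run used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed) {
  manifest <- list(
    package = "olfmap",
    package_version = as.character(utils::packageVersion("olfmap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# consistent CSV writers (UTF-8, "." decimal, header row)
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
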