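#' @importFrom stats aggregate
NULL

#' Read and write multi-page TIFF stacks
#'
#' Images are numeric matrices on the package's 0-255 scale; on disk they are
#' 8-bit grayscale TIFF pages (values are clamped and quantized).
#'
#' @param path TIFF file path.
#' @param imgs list of numeric matrices.
#' @return `read_tiff_stack`: a list of numeric matrices (0-255 scale).
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]    # grayscale from RGB if needed
    p * 255
  })
}

#' @rdname read_tiff_stack
#' @export
write_tiff_stack <- function(imgs, path) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  pages <- lapply(imgs, function(m) {
    m[is.na(m)] <- 0
    pmin(pmax(m / 255, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a pre-extracted trajectory table
#'
#' Columns `t`, `x`, `y` (and optionally `valid`); the frame rate is taken
#' from the time column's spacing unless given.
#'
#' @param path CSV path.
#' @param fps frames per second; default inferred from `t`.
#' @return a `trajectory_track` data.frame.
#' @export
read_track_csv <- function(path, fps = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "x", "y") %in% names(df)))
  if (!"valid" %in% names(df)) df$valid <- TRUE
  if (is.null(fps)) fps <- 1 / stats::median(diff(df$t))
  attr(df, "fps") <- fps
  class(df) <- c("trajectory_track", "data.frame")
  df
}

#' Write column counts, histograms, and aversion results
#'
#' Plain-CSV / JSON writers for the pipeline's tabular outputs.
#'
#' @param counts a `column_counts` data.frame.
#' @param hist a `response_histogram`.
#' @param result an `aversion_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_column_counts <- function(counts, path) {
  write_table_csv(as.data.frame(counts), path)
}

#' @rdname write_column_counts
#' @export
write_histogram_csv <- function(hist, path) {
  write_table_csv(data.frame(class = c("weak", "medium", "high"),
                             columns = c(hist$weak, hist$medium, hist$high)),
                  path)
}

#' @rdname write_column_counts
#' @export
write_aversion_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
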