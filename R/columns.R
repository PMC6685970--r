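#' Bin detected cells into 100-um columns along the unrolled layer
#'
#' Column `j` (0-based) collects particles with arc coordinate
#' `x_um` in `[j*w, (j+1)*w)` (half-open), per sheet row.
#'
#' @param particles a `particle_set` (needs `x_um` and `sheet`).
#' @param column_width column width in micrometres (default 100).
#' @param n_columns optional per-map column count; defaults to the smallest
#'   count covering the data.
#' @return data.frame of class `column_counts`: `row` (sheet), `column`
#'   (0-based), `count`; every (row, column) cell present, zero-filled.
#'   Attribute `column_width`.
#' @export
bin_columns <- function(particles, column_width = 100, n_columns = NULL) {
  stopifnot(column_width > 0)
  if (nrow(particles) > 0 && any(particles$x_um < 0))
    stop("negative arc coordinates: particles upstream of the ventral opening")
  rows <- sort(unique(particles$sheet))
  if (!length(rows)) rows <- 1L
  if (is.null(n_columns)) {
    n_columns <- if (nrow(particles)) max(floor(particles$x_um / column_width)) + 1L else 1L
  }
  grid <- expand.grid(column = seq_len(n_columns) - 1L, row = rows)
  grid <- grid[, c("row", "column")]
  if (nrow(particles)) {
    cc <- data.frame(row = particles$sheet,
                     column = floor(particles$x_um / column_width))
    key <- paste(cc$row, cc$column)
    tab <- table(key)
    grid$count <- as.integer(tab[paste(grid$row, grid$column)])
    grid$count[is.na(grid$count)] <- 0L
  } else {
    grid$count <- 0L
  }
  rownames(grid) <- NULL
  structure(grid, class = c("column_counts", "data.frame"),
            column_width = column_width)
}

#' Classify columns of the OCAM-negative dorsal region into response classes
#'
#' Counts columns by labeled-cell load: weak = 5 to 15 cells, medium = more
#' than 15 up to 25, high = more than 25 ("more than 25" is strict, so a
#' 25-cell column is medium; 15 is assigned to weak so the classes partition).
#' Columns with fewer than 5 cells are left unclassified. Only columns inside
#' the OCAM-negative dorsal interval (boundary columns included) are
#' considered: the unrolled strip runs ventral -> dorsal -> ventral, so the
#' dorsal territory is a central column interval per row.
#'
#' @param counts a `column_counts` data.frame.
#' @param ocam_region data.frame with columns `row`, `lo`, `hi`: the inclusive
#'   0-based column interval of the OCAM-negative dorsal region for each sheet
#'   row. A single `c(lo, hi)` vector is recycled to all rows.
#' @param breaks class boundaries `c(min, weak_hi, medium_hi)`; defaults
#'   `c(5, 15, 25)`: weak = [5, 15], medium = (15, 25], high = (25, Inf).
#' @return list of class `response_histogram`: `weak`, `medium`, `high`
#'   (column counts), `unclassified` (in-region columns with < 5 cells),
#'   `n_region` (columns in the region), `breaks`.
#' @export
classify_columns <- function(counts, ocam_region, breaks = c(5, 15, 25)) {
  stopifnot(inherits(counts, "data.frame"),
            all(c("row", "column", "count") %in% names(counts)))
  rows <- sort(unique(counts$row))
  if (is.numeric(ocam_region) && length(ocam_region) == 2)
    ocam_region <- data.frame(row = rows, lo = ocam_region[1],
                              hi = ocam_region[2])
  stopifnot(all(c("row", "lo", "hi") %in% names(ocam_region)))
  max_col <- max(counts$column)
  if (any(ocam_region$lo < 0) || any(ocam_region$hi > max_col) ||
      any(ocam_region$lo > ocam_region$hi))
    stop("OCAM boundary outside the map")
  reg <- merge(counts, ocam_region, by = "row")
  reg <- reg[reg$column >= reg$lo & reg$column <= reg$hi, ]
  cls <- classify_count(reg$count, breaks)
  structure(list(weak = sum(cls == "weak"),
                 medium = sum(cls == "medium"),
                 high = sum(cls == "high"),
                 unclassified = sum(cls == "unclassified"),
                 n_region = nrow(reg),
                 breaks = breaks),
            class = "response_histogram")
}

# class of a single column count under the weak/medium/high convention
classify_count <- function(count, breaks = c(5, 15, 25)) {
  out <- rep("unclassified", length(count))
  out[count >= breaks[1] & count <= breaks[2]] <- "weak"
  out[count > breaks[2] & count <= breaks[3]] <- "medium"
  out[count > breaks[3]] <- "high"
  out
}

#' Clipped rainbow heat-map raster of per-column cell counts
#'
#' Columns with fewer than 5 cells are drawn black and columns denser than 30
#' red; counts 5..30 follow a linear rainbow scale from blue (5) to red (30).
#'
#' @param counts a `column_counts` data.frame.
#' @param clip `c(low, high)`; below `low` is black, above `high` is red.
#' @param ocam_region optional region (as in [classify_columns()]) whose
#'   boundary columns are marked in the returned metadata.
#' @return character matrix of hex colors (rows = sheet rows, cols = columns),
#'   with attributes `clip` and `boundary` (the region, if given).
#' @export
heatmap_raster <- function(counts, clip = c(5, 30), ocam_region = NULL) {
  rows <- sort(unique(counts$row))
  cols <- 0:max(counts$column)
  pal <- function(v) {
    # linear blue -> red rainbow over [clip[1], clip[2]]
    h <- (4 / 6) * (1 - (v - clip[1]) / (clip[2] - clip[1]))
    grDevices::hsv(h, 1, 1)
  }
  ras <- matrix("#000000", length(rows), length(cols),
                dimnames = list(rows, cols))
  for (i in seq_len(nrow(counts))) {
    v <- counts$count[i]
    col <- if (v < clip[1]) "#000000"
           else if (v > clip[2]) "#FF0000"
           else pal(v)
    ras[match(counts$row[i], rows), counts$column[i] + 1L] <- col
  }
  structure(ras, clip = clip, boundary = ocam_region)
}

#' Write a heat-map raster to PNG
#'
#' @param raster output of [heatmap_raster()].
#' @param path PNG file path.
#' @param cell_px pixels per column cell.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(raster, path, cell_px = 8L) {
  rgb <- grDevices::col2rgb(raster) / 255
  H <- nrow(raster); W <- ncol(raster)
  arr <- array(0, c(H, W, 3))
  for (k in 1:3) arr[, , k] <- matrix(rgb[k, ], H, W)
  big <- arr[rep(seq_len(H), each = cell_px),
             rep(seq_len(W), each = cell_px), , drop = FALSE]
  png::writePNG(big, path)
  invisible(path)
}
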