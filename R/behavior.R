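#' Preprocess one behavioral video frame
#'
#' Auto-threshold to a binary image, apply a 3-pixel Gaussian blur, and
#' re-binarize. The blur removes thin structures — the tail and scattered
#' single-pixel noise — while keeping the body disc. A blank frame yields an
#' empty mask flagged invalid (no error).
#'
#' @param frame numeric matrix (grayscale) or logical matrix (already binary).
#' @param threshold fixed threshold or `"auto"` (Otsu).
#' @param blur_sigma Gaussian blur s.d. in pixels (default 3).
#' @return logical mask with attribute `valid` (FALSE if the frame was blank
#'   or constant).
#' @export
preprocess_frame <- function(frame, threshold = "auto", blur_sigma = 3) {
  if (is.logical(frame)) {
    mask <- frame
  } else {
    th <- if (identical(threshold, "auto")) {
      v <- frame[!is.na(frame)]
      if (diff(range(v)) == 0) {      # blank frame: nothing to segment
        out <- matrix(FALSE, nrow(frame), ncol(frame))
        attr(out, "valid") <- FALSE
        return(out)
      }
      auto_threshold(frame)
    } else threshold
    mask <- !is.na(frame) & frame > th
  }
  if (!any(mask)) {
    attr(mask, "valid") <- FALSE
    return(mask)
  }
  b <- gauss_blur_bbox(mask * 1, blur_sigma)
  out <- b > 0.5
  attr(out, "valid") <- any(out)
  out
}

#' Track the body centroid across frames
#'
#' For each preprocessed frame, labels connected components, keeps those with
#' area inside `size_range`, and takes the area centroid of the largest.
#' Frames with no in-range component are flagged invalid and their centroid
#' is linearly interpolated between valid neighbours. More than
#' `max_invalid_frac` invalid frames is treated as a tracking failure.
#'
#' @param frames one of: a list of numeric matrices, a 3-D array
#'   (rows x cols x frames), or a `function(i)` returning frame `i` (then
#'   `n_frames` is required). Lazy frame functions keep 10-minute videos out
#'   of memory.
#' @param n_frames number of frames when `frames` is a function.
#' @param fps frames per second (for the time axis).
#' @param size_range body-area filter in pixels^2.
#' @param threshold,blur_sigma passed to [preprocess_frame()]. The default
#'   computes one Otsu threshold from the first frame and reuses it (constant
#'   illumination); pass `"auto"` to re-threshold each frame.
#' @return data.frame of class `trajectory_track`: `t`, `x`, `y` (0-based
#'   px), `valid`; attribute `fps`.
#' @export
track_centroid <- function(frames, n_frames = NULL, fps = 25,
                           size_range = c(100, 2000), threshold = NULL,
                           blur_sigma = 3, max_invalid_frac = 0.2) {
  get_frame <- if (is.function(frames)) {
    stopifnot(!is.null(n_frames))
    frames
  } else if (is.array(frames) && length(dim(frames)) == 3) {
    n_frames <- dim(frames)[3]
    function(i) frames[, , i]
  } else {
    n_frames <- length(frames)
    function(i) frames[[i]]
  }
  if (is.null(threshold)) {
    f1 <- get_frame(1)
    threshold <- if (is.logical(f1)) "auto" else auto_threshold(f1)
  }
  xs <- ys <- rep(NA_real_, n_frames)
  for (i in seq_len(n_frames)) {
    mask <- preprocess_frame(get_frame(i), threshold = threshold,
                             blur_sigma = blur_sigma)
    if (!isTRUE(attr(mask, "valid"))) next
    lab <- EBImage::bwlabel(mask * 1)
    if (max(lab) == 0) next
    sizes <- tabulate(lab[lab > 0])
    ok <- which(sizes >= size_range[1] & sizes <= size_range[2])
    if (!length(ok)) next
    body <- ok[which.max(sizes[ok])]
    idx <- which(lab == body, arr.ind = TRUE)
    xs[i] <- mean(idx[, 2] - 1)
    ys[i] <- mean(idx[, 1] - 1)
  }
  valid <- !is.na(xs)
  if (mean(!valid) > max_invalid_frac)
    stop(sprintf("tracking failure: %.1f%% of frames invalid",
                 100 * mean(!valid)))
  if (any(!valid)) {
    ti <- seq_len(n_frames)
    xs <- approx(ti[valid], xs[valid], xout = ti, rule = 2)$y
    ys <- approx(ti[valid], ys[valid], xout = ti, rule = 2)$y
  }
  track <- data.frame(t = (seq_len(n_frames) - 1) / fps, x = xs, y = ys,
                      valid = valid)
  attr(track, "fps") <- fps
  class(track) <- c("trajectory_track", "data.frame")
  track
}

#' Add the normalized distance to the odor source
#'
#' `dhat = |centroid - source| / dist(source, far_line)`: 0 at the source
#' point (the filter paper), 1 on the opposite-side line.
#'
#' @param track a track data.frame with `x`, `y`.
#' @param source `c(x, y)`, same coordinate frame as the centroids.
#' @param far_line either two points (a 2x2 matrix, one point per row)
#'   defining the opposite-side line, or a single number: the perpendicular
#'   distance from the source to that line.
#' @param axis_projection if `TRUE`, use the signed distance along the
#'   source-to-line axis instead of the 2-D Euclidean distance.
#' @return the track with a `dhat` column.
#' @export
normalize_distance <- function(track, source, far_line,
                               axis_projection = FALSE) {
  if (is.matrix(far_line)) {
    p1 <- far_line[1, ]; p2 <- far_line[2, ]
    v <- p2 - p1; v <- v / sqrt(sum(v^2))
    w <- source - p1
    ref <- abs(w[1] * v[2] - w[2] * v[1])     # perpendicular distance
    nrm <- c(-v[2], v[1])                     # unit normal to the line
  } else {
    ref <- far_line
    nrm <- NULL
  }
  if (!is.finite(ref) || ref <= 0)
    stop("zero reference distance between source and far line")
  if (axis_projection) {
    if (is.null(nrm))
      stop("axis projection needs the far line as two points")
    proj <- (track$x - source[1]) * nrm[1] + (track$y - source[2]) * nrm[2]
    track$dhat <- abs(proj) / ref
  } else {
    track$dhat <- sqrt((track$x - source[1])^2 + (track$y - source[2])^2) / ref
  }
  track
}

#' Time spent in a region of normalized distance
#'
#' Counts valid frames with `dhat` below `region` (strict) inside the
#' half-open time window `[window[1], window[2])` and converts to seconds.
#'
#' @param track a track with `dhat` and `valid`; attribute `fps` required.
#' @param region normalized-distance cutoff (default 1/3, the "1/3 area of
#'   the odor source").
#' @param window `c(start, end)` in seconds; default the whole track. A
#'   10-minute trial's "first 1 min" window is `c(0, 60)`.
#' @param far if `TRUE`, count `dhat > 1 - region` instead (the area of the
#'   cage farthest from the source).
#' @return occupancy time in seconds.
#' @export
occupancy <- function(track, region = 1 / 3, window = NULL, far = FALSE) {
  fps <- attr(track, "fps")
  stopifnot(!is.null(fps))
  if (is.null(window)) window <- c(0, max(track$t) + 1 / fps)
  if (window[2] <= window[1]) stop("empty analysis window")
  sel <- track$t >= window[1] & track$t < window[2]
  inreg <- if (far) track$dhat > 1 - region else track$dhat < region
  sum(sel & inreg & track$valid) / fps
}

#' Aversion index of one odor trial
#'
#' `index = T_odor - mean(T_dw)`: the time the animal spent in the near
#' third during the odor trial minus the average time control animals spent
#' there with water. Negative values indicate aversion, positive attraction.
#'
#' @param T_odor seconds in the near region during the odor trial.
#' @param control_T_dw numeric vector of control water-trial times (seconds),
#'   one per control animal; must be non-empty.
#' @param window label for the analysis window (e.g. `"first_1min"`,
#'   `"full_10min"`).
#' @return list of class `aversion_result`: `T_odor`, `T_dw_mean`, `index`,
#'   `n_controls`, `window`.
#' @export
aversion_index <- function(T_odor, control_T_dw, window = "full_10min") {
  if (length(control_T_dw) < 1) stop("at least one control water trial required")
  stopifnot(T_odor >= 0, all(control_T_dw >= 0))
  structure(list(T_odor = T_odor,
                 T_dw_mean = mean(control_T_dw),
                 index = T_odor - mean(control_T_dw),
                 n_controls = length(control_T_dw),
                 window = window),
            class = "aversion_result")
}

#' Per-frame two-area raster data for one animal
#'
#' Every valid frame is assigned to exactly one of two areas: the near third
#' (`dhat < 1/3`) or the remainder. The far third (`dhat > 2/3`) is also
#' reported for the farthest-area analyses.
#'
#' @param track a track with `dhat`.
#' @return data.frame `t`, `area` (factor near/rest), `far_third` (logical),
#'   `valid`.
#' @export
raster_data <- function(track) {
  data.frame(t = track$t,
             area = factor(ifelse(track$dhat < 1 / 3, "near", "rest"),
                           levels = c("near", "rest")),
             far_third = track$dhat > 2 / 3,
             valid = track$valid)
}

#' Positional heat map over the trial window
#'
#' 2-D histogram of the valid per-frame positions; bin sums equal the number
#' of valid frames in the window.
#'
#' @param track a track with `x`, `y`, `valid`.
#' @param bins `c(nx, ny)` histogram resolution.
#' @param range_x,range_y position ranges; default the data range.
#' @param window optional `c(start, end)` seconds.
#' @return matrix of frame counts (rows = y bins, cols = x bins) with
#'   attributes `xbreaks`, `ybreaks`.
#' @export
position_heatmap <- function(track, bins = c(32, 20), range_x = NULL,
                             range_y = NULL, window = NULL) {
  sel <- track$valid
  if (!is.null(window)) sel <- sel & track$t >= window[1] & track$t < window[2]
  x <- track$x[sel]; y <- track$y[sel]
  if (is.null(range_x)) range_x <- range(x)
  if (is.null(range_y)) range_y <- range(y)
  xb <- seq(range_x[1], range_x[2], length.out = bins[1] + 1)
  yb <- seq(range_y[1], range_y[2], length.out = bins[2] + 1)
  ix <- pmin(findInterval(x, xb, rightmost.closed = TRUE), bins[1])
  iy <- pmin(findInterval(y, yb, rightmost.closed = TRUE), bins[2])
  h <- matrix(0L, bins[2], bins[1])
  for (k in seq_along(ix)) h[iy[k], ix[k]] <- h[iy[k], ix[k]] + 1L
  structure(h, xbreaks = xb, ybreaks = yb)
}
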