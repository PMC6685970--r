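#' Trace the glomerular-layer centerline of a section
#'
#' Thresholds the section, keeps the largest connected component (the layer
#' band), and finds its medial path by polar ridge tracing: rays are cast from
#' the band centroid at a fine angular resolution and the band's radial
#' midpoint is taken on each ray. The path is opened at the ventral edge
#' reference point and ordered in the direction of increasing angle (ventral
#' -> medial -> dorsal -> lateral for a coronal bulb section viewed with
#' dorsal up), so that the dorsal-medial reference point maps to a stored
#' landmark arc length.
#'
#' An operator-supplied polyline (the manual ImageJ-style workflow) can be
#' passed instead via `manual`; it is then only opened/ordered and measured.
#'
#' @param img numeric matrix, the section image.
#' @param scale micrometres per pixel.
#' @param ref_ventral,ref_dorsal reference points `c(x, y)` in 0-based pixels:
#'   the ventral edge (opening point) and the dorsal-medial edge (landmark).
#' @param threshold intensity threshold separating the band from background;
#'   `NULL` uses the automatic Otsu threshold.
#' @param n_angles angular resolution of the ridge trace.
#' @param smooth_harmonics Fourier harmonics kept when low-pass smoothing the
#'   traced ridge radius (0 disables smoothing). The default keeps shapes up
#'   to fairly lobed outlines while suppressing pixelation noise.
#' @param section_id label used in error messages.
#' @param manual optional data.frame/matrix with columns `x`, `y`: a
#'   user-traced centerline polyline (0-based px) forming a closed loop.
#' @return object of class `centerline_path`: a list with `x`, `y` (0-based
#'   px), `s_um` (arc length from the ventral opening), `landmark_s_um`,
#'   `scale`, `perimeter_um`.
#' @export
trace_centerline <- function(img, scale, ref_ventral, ref_dorsal,
                             threshold = NULL, n_angles = 1440L,
                             smooth_harmonics = 24L,
                             section_id = "section", manual = NULL) {
  stopifnot(scale > 0, length(ref_ventral) == 2, length(ref_dorsal) == 2)
  if (is.null(manual)) {
    if (is.null(threshold)) threshold <- auto_threshold(img)
    mask <- !is.na(img) & img > threshold
    if (!any(mask))
      stop(sprintf("tracing failed for %s: no foreground at threshold %.3g",
                   section_id, threshold))
    # 8-connected components: label the 3x3-dilated mask, measure on the
    # original (a 1-px digital ring is 8- but not 4-connected)
    lab <- EBImage::bwlabel(EBImage::dilate(mask * 1,
                                            EBImage::makeBrush(3, "box")))
    sizes <- tabulate(lab[mask])
    band <- mask & (lab == which.max(sizes))
    idx <- which(band, arr.ind = TRUE)
    cx <- mean(idx[, 2] - 1); cy <- mean(idx[, 1] - 1)

    # polar ridge: on each ray find the in-band radial run containing the
    # expected layer, take its midpoint (subpixel via fine radial sampling)
    phi_v <- atan2(ref_ventral[2] - cy, ref_ventral[1] - cx)
    phi <- phi_v + 2 * pi * (seq_len(n_angles) - 1L) / n_angles
    rmax <- sqrt(max((idx[, 2] - 1 - cx)^2 + (idx[, 1] - 1 - cy)^2)) + 2
    rstep <- 0.25
    rr <- seq(rstep, rmax, by = rstep)
    bandm <- band * 1
    mid_r <- vapply(phi, function(a) {
      vals <- bilinear(bandm, cx + rr * cos(a), cy + rr * sin(a))
      v <- vals > 0.5
      # a band thinner than the sampling kernel (e.g. a 1-px ring) may never
      # reach 0.5 under bilinear interpolation; relax symmetrically
      if (!any(v)) v <- vals > 0.05
      if (!any(v)) return(NA_real_)
      runs <- rle(v)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      on <- which(runs$values)
      # widest run = the layer band (robust to specks)
      k <- on[which.max(runs$lengths[on])]
      (rr[starts[k]] + rr[ends[k]]) / 2
    }, numeric(1))
    if (anyNA(mid_r))
      stop(sprintf(
        "tracing failed for %s: layer band not connected around the bulb",
        section_id))
    # the layer outline is smooth; low-pass the ridge radius to remove
    # pixelation noise, which would otherwise inflate the arc length
    if (smooth_harmonics > 0 && 2 * smooth_harmonics + 1 < n_angles) {
      f <- stats::fft(mid_r)
      keep <- c(seq_len(smooth_harmonics + 1),
                seq(n_angles - smooth_harmonics + 1, n_angles))
      f[-keep] <- 0
      mid_r <- Re(stats::fft(f, inverse = TRUE)) / n_angles
    }
    x <- cx + mid_r * cos(phi)
    y <- cy + mid_r * sin(phi)
  } else {
    manual <- as.data.frame(manual)
    x <- manual$x; y <- manual$y
    cx <- mean(x); cy <- mean(y)
    phi <- atan2(y - cy, x - cx)
    phi_v <- atan2(ref_ventral[2] - cy, ref_ventral[1] - cx)
    ord <- order((phi - phi_v) %% (2 * pi))
    x <- x[ord]; y <- y[ord]
  }

  # reference points must lie near the traced band
  d_v <- min(sqrt((x - ref_ventral[1])^2 + (y - ref_ventral[2])^2))
  d_d <- min(sqrt((x - ref_dorsal[1])^2 + (y - ref_dorsal[2])^2))
  tol <- max(10, 3 / scale)
  if (d_v > tol || d_d > tol)
    stop(sprintf("tracing failed for %s: reference point %.1f px from the traced band",
                 section_id, max(d_v, d_d)))

  seg <- sqrt(diff(x)^2 + diff(y)^2) * scale
  s <- c(0, cumsum(seg))
  d_dm <- sqrt((x - ref_dorsal[1])^2 + (y - ref_dorsal[2])^2)
  structure(list(x = x, y = y, s_um = s,
                 landmark_s_um = s[which.min(d_dm)],
                 scale = scale,
                 perimeter_um = s[length(s)] +
                   sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2) * scale),
            class = "centerline_path")
}

#' Straighten a curved layer into a flat strip
#'
#' Resamples the image along normals to the centerline at 1-pixel arc steps
#' (bilinear interpolation), the curved-layer analogue of the ImageJ
#' "straighten" operation. Strip column `j` (0-based) corresponds to arc
#' length `j * scale` micrometres from the ventral opening; the strip's
#' central row corresponds to the path itself, and row offsets follow the
#' path's left normal (so a straight horizontal path reproduces an
#' axis-aligned crop exactly).
#'
#' @param img numeric matrix, the section image.
#' @param path a `centerline_path` (or any list with `x`, `y`, `s_um`,
#'   `landmark_s_um`, `scale`).
#' @param half_width half-width of the strip in micrometres; must cover the
#'   layer.
#' @return object of class `unrolled_sheet`: a numeric matrix
#'   (rows = 2*hw_px+1 across-layer, cols = arc steps) with attributes
#'   `scale`, `landmark_x` (0-based strip column of the dorsal-medial
#'   landmark), `half_width_um`, and `n_outside` (samples that fell outside
#'   the image, filled with 0 and counted).
#' @export
straighten <- function(img, path, half_width) {
  stopifnot(half_width > 0)
  scale <- path$scale
  hw <- round(half_width / scale)
  n_steps <- floor(path$s_um[length(path$s_um)] / scale) + 1L
  s_px <- (seq_len(n_steps) - 1L) * scale
  xs <- approx(path$s_um, path$x, xout = s_px)$y
  ys <- approx(path$s_um, path$y, xout = s_px)$y
  # tangents by central differences on the resampled path
  tx <- c(xs[2] - xs[1], (xs[-(1:2)] - xs[seq_len(n_steps - 2L)]) / 2,
          xs[n_steps] - xs[n_steps - 1L])
  ty <- c(ys[2] - ys[1], (ys[-(1:2)] - ys[seq_len(n_steps - 2L)]) / 2,
          ys[n_steps] - ys[n_steps - 1L])
  tl <- pmax(sqrt(tx^2 + ty^2), 1e-12)
  nx <- -ty / tl; ny <- tx / tl            # +90 degree rotation, y-down coords
  off <- seq(-hw, hw)
  PX <- outer(off, nx) ; PX <- sweep(PX, 2, xs, "+")
  PY <- outer(off, ny) ; PY <- sweep(PY, 2, ys, "+")
  outside <- PX < 0 | PX > ncol(img) - 1 | PY < 0 | PY > nrow(img) - 1
  n_out <- sum(outside)
  if (n_out > 0)
    warning(sprintf("straighten: %d samples outside the image, filled as background",
                    n_out))
  strip <- matrix(bilinear(img, as.vector(PX), as.vector(PY)),
                  nrow = length(off))
  structure(strip, class = c("unrolled_sheet", "matrix"),
            scale = scale,
            landmark_x = round(path$landmark_s_um / scale),
            half_width_um = hw * scale,
            n_outside = n_out)
}

#' Assemble straightened sheets into an unrolled odor map
#'
#' Stacks per-section strips anterior (top) to posterior (bottom), shifting
#' each so its dorsal-medial landmark sits at a common x, and padding with an
#' `NA` no-data sentinel (never intensity 0). No intensity value is altered.
#'
#' @param sheets list of `unrolled_sheet` objects in anterior -> posterior
#'   order.
#' @param section_index integer indices of the sections (must be strictly
#'   increasing); defaults to `seq_along(sheets)`.
#' @param section_spacing centre-to-centre spacing between consecutive
#'   sections in micrometres (metadata only).
#' @return list of class `odor_map`: `sheets` (the shifted strips, common
#'   width, NA-padded), `image` (all strips row-bound, NA-padded),
#'   `landmark_x` (common 0-based landmark column), `shift_px` (per-sheet
#'   left pad applied), `scale`, `section_index`, `section_spacing`.
#' @export
assemble_map <- function(sheets, section_index = seq_along(sheets),
                         section_spacing = 80) {
  stopifnot(length(sheets) >= 1)
  if (any(diff(section_index) <= 0))
    stop("section indices must be strictly increasing (anterior -> posterior)")
  lm <- vapply(sheets, function(s) attr(s, "landmark_x"), numeric(1))
  sc <- vapply(sheets, function(s) attr(s, "scale"), numeric(1))
  if (length(unique(round(sc, 9))) != 1)
    stop("sheets have inconsistent pixel scales")
  common_lm <- max(lm)
  shift <- common_lm - lm
  widths <- vapply(sheets, ncol, integer(1)) + shift
  out_w <- max(widths)
  shifted <- mapply(function(s, sh) {
    m <- matrix(NA_real_, nrow(s), out_w)
    m[, (sh + 1):(sh + ncol(s))] <- s
    m
  }, sheets, shift, SIMPLIFY = FALSE)
  structure(list(sheets = shifted,
                 image = do.call(rbind, shifted),
                 landmark_x = common_lm,
                 shift_px = shift,
                 scale = sc[1],
                 section_index = section_index,
                 section_spacing = section_spacing),
            class = "odor_map")
}
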