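# shared fixture builders (everything is generated in code at test time)

# paint uniform-intensity discs onto a background matrix; centres are 0-based
paint_discs <- function(img, centres, r, fg = 200) {
  for (i in seq_len(nrow(centres))) {
    cx <- centres[i, 1]; cy <- centres[i, 2]
    xs <- max(0, floor(cx - r)):min(ncol(img) - 1, ceiling(cx + r))
    ys <- max(0, floor(cy - r)):min(nrow(img) - 1, ceiling(cy + r))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    blk <- img[ys + 1, xs + 1, drop = FALSE]
    blk[d2 <= r^2] <- fg
    img[ys + 1, xs + 1] <- blk
  }
  img
}

# analytic annular band image: bright where rin <= dist(centre) <= rout
annulus_image <- function(size, centre, rin, rout, fg = 110, bg = 0) {
  x <- matrix(rep(0:(size[1] - 1), each = size[2]), size[2], size[1])
  y <- matrix(rep(0:(size[2] - 1), size[1]), size[2], size[1])
  r <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
  img <- matrix(bg, size[2], size[1])
  img[r >= rin & r <= rout] <- fg
  img
}

# a straight horizontal centerline path (for the identity/crop case)
straight_path <- function(x0, x1, y, scale = 1) {
  xs <- x0:x1
  structure(list(x = xs, y = rep(y, length(xs)),
                 s_um = (xs - x0) * scale, landmark_s_um = 0,
                 scale = scale, perimeter_um = (x1 - x0) * scale),
            class = "centerline_path")
}

# the "cleanly separable" synthetic section preset used by recovery tests
clean_section_spec <- function(seed, ...) {
  section_spec(a = 350, b = 280, width = 40, lambda = 12,
               nucleus_radius = 6, size = c(860, 720),
               min_sep = 16, column_guard = 8, seed = seed, ...)
}

# run one section through the full unrolling + counting pipeline
run_section_pipeline <- function(sec, half_width = 26, size_range = c(30, 260),
                                 sheet_index = 1L) {
  sp <- sec$spec
  path <- trace_centerline(sec$image, sp$scale, sec$refs$ventral,
                           sec$refs$dorsal_medial)
  sheet <- straighten(sec$image, path, half_width = half_width)
  detect_cells(sheet, size_range = size_range, sheet_index = sheet_index)
}

# a synthetic track data.frame with given dhat values at a given fps
synth_track <- function(dhat, fps = 25) {
  tr <- data.frame(t = (seq_along(dhat) - 1) / fps,
                   x = 0, y = 0, dhat = dhat, valid = TRUE)
  attr(tr, "fps") <- fps
  tr
}
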