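#' Specification for one synthetic olfactory-bulb section image
#'
#' Describes an annular glomerular-layer band around an elliptical centerline,
#' with labeled nuclei placed along it at an angle-dependent Poisson density.
#' The rendered image emulates a chromogenically labeled coronal section:
#' a Gaussian-noise background with uniform-intensity nucleus discs.
#'
#' Geometry convention: image x grows rightward, y downward; the centerline is
#' parameterized by an angle `theta` with the ventral (bottom) point at
#' `theta = pi/2`, and arc length measured from the ventral opening in the
#' direction of increasing `theta` (ventral -> medial -> dorsal -> lateral).
#' The dorsal-medial landmark sits at `theta = 5*pi/4` and the dorsal pole at
#' `theta = 3*pi/2`.
#'
#' @param a,b ellipse semi-axes of the layer centerline (micrometres).
#' @param width full across-layer width of the glomerular band (micrometres).
#' @param lambda expected nuclei per 100 micrometres of arc: a constant or a
#'   function of `theta` (radians) returning a non-negative density.
#' @param nucleus_radius nucleus disc radius in pixels.
#' @param theta_ocam half-angle (radians) of the OCAM-negative dorsal sector,
#'   centred on the dorsal pole. Columns inside it form the quantified region.
#' @param noise_sd background Gaussian noise s.d. (intensity units, 0-255 scale).
#' @param band_intensity intensity of the glomerular-layer band tissue
#'   (between background and nuclei), so thresholding the section yields a
#'   connected annular band as in a stained section.
#' @param scale pixel scale, micrometres per pixel.
#' @param size image size in pixels, `c(width, height)`.
#' @param jitter amplitude (micrometres) of a smooth periodic radial
#'   perturbation of the centerline; 0 gives the exact ellipse.
#' @param bg_mean,fg_intensity background mean and nucleus intensity (0-255).
#' @param min_sep minimum centre-to-centre nucleus separation (micrometres);
#'   0 disables the constraint (pure Poisson placement).
#' @param column_guard minimum distance (micrometres) of a nucleus centre from
#'   any 100-um column boundary; 0 disables. Used by the "cleanly separable"
#'   preset so that every blob lies wholly inside one column.
#' @param touching_frac fraction of nuclei that receive a twin placed 1.5 radii
#'   away (a touching pair the watershed must split).
#' @param seed integer RNG seed.
#' @return an object of class `section_spec`.
#' @export
section_spec <- function(a = 400, b = 300, width = 40, lambda = 15,
                         nucleus_radius = 3, theta_ocam = pi / 3,
                         noise_sd = 5, scale = 1, size = c(960, 768),
                         jitter = 0, bg_mean = 50, fg_intensity = 200,
                         band_intensity = 110,
                         min_sep = 0, column_guard = 0, touching_frac = 0,
                         seed = 1L) {
  stopifnot(a > 0, b > 0, width > 0, scale > 0, nucleus_radius > 0,
            noise_sd >= 0, length(size) == 2, all(size > 0),
            touching_frac >= 0, touching_frac <= 1)
  lam <- if (is.function(lambda)) lambda else function(theta) rep(lambda, length(theta))
  if (any(lam(seq(0, 2 * pi, length.out = 64)) < 0))
    stop("lambda(theta) must be non-negative everywhere")
  structure(list(a = a, b = b, width = width, lambda = lam,
                 nucleus_radius = nucleus_radius, theta_ocam = theta_ocam,
                 noise_sd = noise_sd, scale = scale, size = as.integer(size),
                 jitter = jitter, bg_mean = bg_mean,
                 fg_intensity = fg_intensity, band_intensity = band_intensity,
                 min_sep = min_sep,
                 column_guard = column_guard, touching_frac = touching_frac,
                 seed = as.integer(seed)),
            class = "section_spec")
}

# Centerline sample on a fine theta grid starting at the ventral opening.
# Returns 0-based pixel coordinates, theta, and cumulative arc length (um).
centerline_grid <- function(spec, n = 4096L, jitter_coef = NULL) {
  theta_v <- pi / 2
  theta <- theta_v + 2 * pi * (seq_len(n) - 1L) / n
  cx <- (spec$size[1] - 1) / 2
  cy <- (spec$size[2] - 1) / 2
  jit <- numeric(n)
  if (spec$jitter > 0) {
    # smooth periodic radial perturbation, harmonics 2..5
    if (is.null(jitter_coef)) jitter_coef <- rnorm(8)
    for (h in 2:5) {
      jit <- jit + jitter_coef[h - 1] * cos(h * theta) +
                   jitter_coef[h + 3] * sin(h * theta)
    }
    jit <- spec$jitter * jit / max(abs(jit), 1e-12)
  }
  x <- cx + (spec$a * cos(theta) + jit * cos(theta)) / spec$scale
  y <- cy + (spec$b * sin(theta) + jit * sin(theta)) / spec$scale
  seg <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2) * spec$scale
  s <- c(0, cumsum(seg))                      # length n + 1; s[n+1] = perimeter
  list(theta = theta, x = x, y = y, s = s[seq_len(n)], perimeter = s[n + 1L],
       cx = cx, cy = cy)
}

#' Generate a synthetic section image with exact ground truth
#'
#' Nuclei counts per angular bin are Poisson with mean
#' `lambda(theta) * arc_length / 100`; each nucleus is placed uniformly along
#' its bin's arc and uniformly across the band (kept fully inside it), then
#' rendered as a uniform-intensity disc over Gaussian background noise. The
#' ground truth lists every nucleus with its arc-length coordinate and true
#' 100-um column.
#'
#' @param spec a [section_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{image}{numeric matrix (height x width), 0-255 scale}
#'     \item{nuclei}{data.frame: `x`, `y` (0-based px), `s_um` (arc length from
#'       the ventral opening), `theta`, `column` (0-based 100-um column index),
#'       `pair` (TRUE for the twin of a touching pair)}
#'     \item{centerline}{data.frame `x`, `y`, `s_um` of the true centerline}
#'     \item{refs}{list with `ventral` and `dorsal_medial` reference points
#'       (0-based px) and `landmark_s_um`, the arc position of the landmark}
#'     \item{ocam}{list `lo`, `hi`: inclusive 0-based column interval of the
#'       OCAM-negative dorsal region, and the sector angles}
#'     \item{expected_columns}{data.frame `column`, `expected`: the Poisson
#'       mean per 100-um column}
#'     \item{spec}{the input spec}
#'   }
#' @export
gen_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  set.seed(spec$seed)
  g <- centerline_grid(spec)
  half_band_px <- (spec$width / 2) / spec$scale + spec$nucleus_radius + 1
  if (any(g$x - half_band_px < 0) || any(g$x + half_band_px > spec$size[1] - 1) ||
      any(g$y - half_band_px < 0) || any(g$y + half_band_px > spec$size[2] - 1))
    stop("layer band exceeds image bounds: enlarge `size` or shrink a/b/width")

  n <- length(g$theta)
  ds <- diff(c(g$s, g$perimeter))
  lam_bin <- spec$lambda((g$theta + c(g$theta[-1], g$theta[1] + 2 * pi)) / 2) * ds / 100
  counts <- rpois(n, lam_bin)

  r_um <- spec$nucleus_radius * spec$scale
  max_off <- spec$width / 2 - r_um
  if (max_off < 0) stop("nucleus radius exceeds the half band width")

  place_one <- function(bin) {
    for (try in 1:400) {
      s_n <- g$s[bin] + runif(1) * ds[bin]
      if (spec$column_guard > 0) {
        dmod <- s_n %% 100
        if (min(dmod, 100 - dmod) < spec$column_guard) next
        # also keep clear of the ventral opening (the strip's two cut ends)
        if (min(s_n, g$perimeter - s_n) < spec$column_guard +
              spec$nucleus_radius * spec$scale) next
      }
      return(s_n)
    }
    NA_real_   # guard too tight for this bin; drop the nucleus
  }

  # separation is checked in band coordinates (arc s, radial offset), a good
  # local approximation to 2-D distance near the centerline
  s_all <- off_all <- numeric(0); pair_flag <- logical(0)
  for (bin in which(counts > 0)) {
    for (k in seq_len(counts[bin])) {
      placed <- FALSE
      for (try in 1:400) {
        s_n <- place_one(bin)
        if (is.na(s_n)) break
        o_n <- runif(1, -max_off, max_off)
        if (spec$min_sep > 0 && length(s_all) > 0) {
          d2 <- pmin(abs(s_all - s_n), g$perimeter - abs(s_all - s_n))^2 +
                (off_all - o_n)^2
          if (min(d2) < spec$min_sep^2) next
        }
        s_all <- c(s_all, s_n); off_all <- c(off_all, o_n)
        pair_flag <- c(pair_flag, FALSE); placed <- TRUE
        break
      }
    }
  }
  # touching pairs: a twin offset ~1.5 radii along the band
  if (spec$touching_frac > 0 && length(s_all) > 0) {
    idx <- which(runif(length(s_all)) < spec$touching_frac & !pair_flag)
    for (i in idx) {
      s_all <- c(s_all, s_all[i] + 1.5 * r_um * sample(c(-1, 1), 1))
      off_all <- c(off_all, off_all[i])
      pair_flag <- c(pair_flag, TRUE)
    }
    s_all <- pmin(pmax(s_all, 0), g$perimeter - 1e-9)
  }

  ord <- order(s_all)
  s_all <- s_all[ord]; off_all <- off_all[ord]; pair_flag <- pair_flag[ord]
  m <- length(s_all)

  # map arc position -> point + outward unit normal on the fine grid
  interp_xy <- function(s_q) {
    xs <- approx(c(g$s, g$perimeter), c(g$x, g$x[1]), xout = s_q)$y
    ys <- approx(c(g$s, g$perimeter), c(g$y, g$y[1]), xout = s_q)$y
    cbind(xs, ys)
  }
  if (m > 0) {
    p  <- interp_xy(s_all)
    eps <- 0.5 * spec$scale
    pf <- interp_xy(pmin(s_all + eps, g$perimeter))
    pb <- interp_xy(pmax(s_all - eps, 0))
    tg <- pf - pb
    tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
    nrm <- cbind(-tg[, 2], tg[, 1])           # rotate tangent by +90 deg (y down)
    # ensure outward orientation
    outward <- cbind(p[, 1] - g$cx, p[, 2] - g$cy)
    flip <- rowSums(nrm * outward) < 0
    nrm[flip, ] <- -nrm[flip, ]
    px <- p[, 1] + (off_all / spec$scale) * nrm[, 1]
    py <- p[, 2] + (off_all / spec$scale) * nrm[, 2]
  } else {
    px <- py <- numeric(0)
  }

  nuclei <- data.frame(x = px, y = py, s_um = s_all,
                       theta = pi / 2 + 2 * pi * s_all / g$perimeter,
                       column = floor(s_all / 100), pair = pair_flag)

  # render: Gaussian background + the layer band tissue + hard nucleus discs.
  # The band is rasterized in polar coordinates, symmetric about the
  # centerline, so its radial midpoint is the centerline itself.
  W <- spec$size[1]; H <- spec$size[2]
  img <- matrix(rnorm(H * W, spec$bg_mean, spec$noise_sd), H, W)
  pxx <- matrix(rep(0:(W - 1), each = H), H, W)
  pyy <- matrix(rep(0:(H - 1), W), H, W)
  phi_pix <- atan2(pyy - g$cy, pxx - g$cx)
  r_pix <- sqrt((pxx - g$cx)^2 + (pyy - g$cy)^2)
  phi_grid <- atan2(g$y - g$cy, g$x - g$cx)
  rel <- (phi_grid - phi_grid[1]) %% (2 * pi)
  ordg <- order(rel)
  rc_of_phi <- approx(c(rel[ordg], 2 * pi),
                      c(sqrt((g$x - g$cx)^2 + (g$y - g$cy)^2)[ordg],
                        sqrt((g$x[ordg[1]] - g$cx)^2 + (g$y[ordg[1]] - g$cy)^2)),
                      xout = (phi_pix - phi_grid[1]) %% (2 * pi))$y
  hw_band <- (spec$width / 2) / spec$scale + spec$nucleus_radius
  in_band <- abs(r_pix - rc_of_phi) <= hw_band
  img[in_band] <- spec$band_intensity +
    rnorm(sum(in_band), 0, spec$noise_sd)
  r <- spec$nucleus_radius
  for (i in seq_len(m)) {
    c0 <- max(0, floor(px[i] - r)); c1 <- min(W - 1, ceiling(px[i] + r))
    r0 <- max(0, floor(py[i] - r)); r1 <- min(H - 1, ceiling(py[i] + r))
    xs <- c0:c1; ys <- r0:r1
    d2 <- outer((ys - py[i])^2, (xs - px[i])^2, "+")
    blk <- img[ys + 1, xs + 1, drop = FALSE]
    blk[d2 <= r^2] <- spec$fg_intensity
    img[ys + 1, xs + 1] <- blk
  }

  s_at_theta <- function(th) approx(g$theta, g$s, xout = th)$y
  lm_idx <- which.min(abs(g$theta - 5 * pi / 4))
  dm_ref <- c(g$x[lm_idx], g$y[lm_idx])
  v_ref  <- c(g$x[1], g$y[1])

  th_d <- 3 * pi / 2
  ocam <- list(lo = floor(s_at_theta(th_d - spec$theta_ocam) / 100),
               hi = floor(s_at_theta(th_d + spec$theta_ocam) / 100),
               theta_lo = th_d - spec$theta_ocam,
               theta_hi = th_d + spec$theta_ocam)

  ncol_map <- ceiling(g$perimeter / 100)
  col_edges <- seq(0, by = 100, length.out = ncol_map + 1)
  exp_counts <- vapply(seq_len(ncol_map), function(j) {
    inbin <- g$s >= col_edges[j] & g$s < col_edges[j + 1]
    sum(lam_bin[inbin])
  }, numeric(1))

  list(image = img, nuclei = nuclei,
       centerline = data.frame(x = g$x, y = g$y, s_um = g$s),
       refs = list(ventral = v_ref, dorsal_medial = dm_ref,
                   landmark_s_um = g$s[lm_idx]),
       ocam = ocam,
       expected_columns = data.frame(column = seq_len(ncol_map) - 1L,
                                     expected = exp_counts),
       spec = spec)
}
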