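#' Specification of a synthetic innate-aversion trial
#'
#' A mouse explores a rectangular cage as a reflected random walk with an
#' optional drift away from an odor source; the drift decays exponentially
#' with distance. Frames can be rendered (body disc plus a thin tail) to
#' exercise the video-tracking pipeline.
#'
#' The defaults mirror the recording setup: a 200 x 318 mm cage filmed at
#' 25 frames/s with 320 x 180-pixel frames, 10-minute trials, the odor
#' source (filter paper) at the middle of one short wall.
#'
#' @param cage cage floor size `c(width, length)` in mm.
#' @param fps frame rate, frames per second.
#' @param frame_size rendered frame size `c(width, height)` in pixels.
#' @param duration trial length in seconds.
#' @param source odor-source point `c(x, y)` in mm.
#' @param beta drift strength, mm per frame step; 0 = indifferent, larger =
#'   stronger avoidance.
#' @param lambda_odor length scale (mm) of the drift's exponential decay
#'   with distance from the source.
#' @param sigma step noise s.d. in mm per frame (isotropic). The default,
#'   2.5 mm at 25 fps, corresponds to a ~60 mm/s exploration speed.
#' @param body_radius rendered body disc radius in pixels.
#' @param tail_length rendered tail length in pixels (1 px wide, so the
#'   documented 3-px blur removes it).
#' @param start start position in mm; default cage centre.
#' @param seed integer RNG seed.
#' @return object of class `behavior_spec`.
#' @export
behavior_spec <- function(cage = c(200, 318), fps = 25, frame_size = c(320, 180),
                          duration = 600, source = c(100, 0), beta = 0,
                          lambda_odor = 30, sigma = 2.5, body_radius = 8,
                          tail_length = 14, start = NULL, seed = 1L) {
  stopifnot(duration > 0, fps > 0, sigma > 0, beta >= 0, lambda_odor > 0,
            all(cage > 0), all(frame_size > 0))
  if (is.null(start)) start <- cage / 2
  structure(list(cage = cage, fps = fps, frame_size = as.integer(frame_size),
                 duration = duration, source = source, beta = beta,
                 lambda_odor = lambda_odor, sigma = sigma,
                 body_radius = body_radius, tail_length = tail_length,
                 start = start, seed = as.integer(seed)),
            class = "behavior_spec")
}

# mm -> rendered-frame px mapping (isotropic, cage centred in the frame)
frame_calibration <- function(spec) {
  margin <- spec$body_radius + 2
  s <- min((spec$frame_size[1] - 1 - 2 * margin) / spec$cage[1],
           (spec$frame_size[2] - 1 - 2 * margin) / spec$cage[2])
  off <- (spec$frame_size - 1 - s * spec$cage) / 2
  list(px_per_mm = s, offset = off)
}

#' Simulate a trial trajectory (and optionally render its frames)
#'
#' The track is a discrete-time biased random walk:
#' `x[t+1] = reflect(x[t] + beta * exp(-d/lambda_odor) * u_away + sigma * eps)`
#' with standard bivariate normal `eps`, reflected so the body stays inside
#' the cage. Ground-truth normalized distance and near-region occupancy come
#' from this continuous track.
#'
#' @param spec a [behavior_spec()].
#' @return list with
#'   \describe{
#'     \item{track}{data.frame `t` (s), `x`, `y` (mm), `dhat` (normalized
#'       distance: 0 at the source, 1 at the opposite wall), `valid`}
#'     \item{calibration}{mm -> px mapping for rendered frames}
#'     \item{render_frame}{`function(i)` returning frame `i` as a numeric
#'       matrix (0-255 scale); frames are rendered lazily, one at a time}
#'     \item{n_frames}{number of frames}
#'     \item{spec}{the input spec}
#'   }
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  cal <- frame_calibration(spec)
  r_mm <- spec$body_radius / cal$px_per_mm
  if (2 * spec$body_radius >= min(spec$frame_size))
    stop("body radius larger than the frame")
  lo <- c(r_mm, r_mm); hi <- spec$cage - r_mm

  set.seed(spec$seed)
  n <- round(spec$duration * spec$fps)
  pos <- matrix(0, n, 2)
  pos[1, ] <- pmin(pmax(spec$start, lo), hi)
  eps <- matrix(rnorm(2 * (n - 1), 0, spec$sigma), n - 1, 2)
  reflect1 <- function(v, a, b) {
    # fold into [a, b] (at most a few bounces for realistic steps)
    while (v < a || v > b) {
      if (v < a) v <- 2 * a - v
      if (v > b) v <- 2 * b - v
    }
    v
  }
  for (t in seq_len(n - 1)) {
    dvec <- pos[t, ] - spec$source
    d <- sqrt(sum(dvec^2))
    drift <- if (d > 1e-9) spec$beta * exp(-d / spec$lambda_odor) * dvec / d
             else c(0, 0)
    nxt <- pos[t, ] + drift + eps[t, ]
    pos[t + 1, 1] <- reflect1(nxt[1], lo[1], hi[1])
    pos[t + 1, 2] <- reflect1(nxt[2], lo[2], hi[2])
  }
  # random per-frame tail direction (smoothed), drawn now for reproducibility
  tail_angle <- cumsum(rnorm(n, 0, 0.4)) + runif(1, 0, 2 * pi)

  # normalized distance: far line = long-axis wall opposite the source
  far_dist <- if (spec$source[2] <= spec$cage[2] / 2) spec$cage[2] - spec$source[2]
              else spec$source[2]
  dhat <- sqrt((pos[, 1] - spec$source[1])^2 + (pos[, 2] - spec$source[2])^2) /
          far_dist
  track <- data.frame(t = (seq_len(n) - 1) / spec$fps,
                      x = pos[, 1], y = pos[, 2], dhat = dhat, valid = TRUE)
  attr(track, "fps") <- spec$fps

  render_frame <- function(i) {
    stopifnot(i >= 1, i <= n)
    W <- spec$frame_size[1]; H <- spec$frame_size[2]
    # deterministic per-frame noise, independent of when the frame is drawn
    frame_seed <- (as.numeric(spec$seed) * 1000003 + i) %% 2147483647
    set.seed(as.integer(frame_seed))
    f <- matrix(rnorm(H * W, 25, 3), H, W)
    cpx <- cal$offset + cal$px_per_mm * c(track$x[i], track$y[i])
    r <- spec$body_radius
    c0 <- max(0, floor(cpx[1] - r)); c1 <- min(W - 1, ceiling(cpx[1] + r))
    r0 <- max(0, floor(cpx[2] - r)); r1 <- min(H - 1, ceiling(cpx[2] + r))
    xs <- c0:c1; ys <- r0:r1
    d2 <- outer((ys - cpx[2])^2, (xs - cpx[1])^2, "+")
    blk <- f[ys + 1, xs + 1, drop = FALSE]
    blk[d2 <= r^2] <- 230
    f[ys + 1, xs + 1] <- blk
    # 1-px-wide tail from the body edge
    a <- tail_angle[i]
    tpts <- seq(r + 0.5, r + spec$tail_length, by = 0.7)
    tx <- round(cpx[1] + tpts * cos(a)); ty <- round(cpx[2] + tpts * sin(a))
    ok <- tx >= 0 & tx < W & ty >= 0 & ty < H
    f[cbind(ty[ok] + 1, tx[ok] + 1)] <- 230
    f
  }

  list(track = track, calibration = cal, render_frame = render_frame,
       n_frames = n, spec = spec)
}
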