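test_that("frame preprocessing keeps the body and removes tail and noise", {
  set.seed(3)
  frame <- matrix(rnorm(180 * 320, 25, 3), 180, 320)
  frame <- paint_discs(frame, cbind(160, 90), r = 8, fg = 230)
  body_area <- sum(frame == 230)
  # 1-px-wide tail
  tx <- round(160 + 9:22); ty <- rep(90, length(tx))
  frame[cbind(ty + 1, tx + 1)] <- 230
  # scattered 1-px noise
  frame[cbind(c(10, 170, 40), c(10, 300, 250)) ] <- 230

  mask <- preprocess_frame(frame)
  expect_true(attr(mask, "valid"))
  # tail gone: no foreground beyond the disc's right edge
  expect_equal(sum(mask[, (160 + 12):320]), 0)
  # scattered specks gone
  expect_false(mask[11, 11] || mask[171, 301] || mask[41, 251])
  # body area within 15% of the rendered disc
  expect_lt(abs(sum(mask) - body_area) / body_area, 0.15)

  # blank frame: empty mask flagged invalid, no error
  blank <- matrix(25, 180, 320)
  mb <- preprocess_frame(blank)
  expect_false(attr(mb, "valid"))
  expect_equal(sum(mb), 0)
})

test_that("centroid tracking recovers known positions and filters dust", {
  set.seed(5)
  mk_frame <- function(cx, cy, dust = FALSE) {
    f <- matrix(rnorm(180 * 320, 25, 3), 180, 320)
    f <- paint_discs(f, cbind(cx, cy), r = 8, fg = 230)
    if (dust) f <- paint_discs(f, cbind(30, 30), r = 3, fg = 230)
    f
  }
  cx <- seq(60, 260, length.out = 20); cy <- seq(40, 140, length.out = 20)
  frames <- lapply(1:20, function(i) mk_frame(cx[i], cy[i], dust = i %% 3 == 0))
  tr <- track_centroid(frames, fps = 25, size_range = c(100, 2000))
  expect_lt(max(abs(tr$x - cx)), 0.5)
  expect_lt(max(abs(tr$y - cy)), 0.5)

  # identical frames give a constant track
  same <- track_centroid(rep(list(mk_frame(100, 90)), 5), fps = 25)
  expect_equal(var(same$x), 0)

  # invalid frames are interpolated between valid neighbours and flagged
  frames2 <- frames
  frames2[[10]] <- matrix(25, 180, 320)
  tr2 <- track_centroid(frames2, fps = 25)
  expect_false(tr2$valid[10])
  expect_equal(tr2$x[10], (tr2$x[9] + tr2$x[11]) / 2, tolerance = 0.05)

  # too many invalid frames is a tracking failure
  blanks <- rep(list(matrix(25, 180, 320)), 6)
  expect_error(track_centroid(c(frames[1:10], blanks), fps = 25), "tracking")
})

test_that("distance normalization maps source to 0 and far line to 1", {
  tr <- data.frame(t = 0:2 / 25, x = c(0, 100, 50), y = c(0, 0, 0),
                   valid = TRUE)
  attr(tr, "fps") <- 25
  out <- normalize_distance(tr, source = c(0, 0), far_line = 100)
  expect_equal(out$dhat, c(0, 1, 0.5))
  # far line given as two points
  out2 <- normalize_distance(tr, source = c(0, 0),
                             far_line = rbind(c(100, -5), c(100, 5)))
  expect_equal(out2$dhat, c(0, 1, 0.5))
  expect_error(normalize_distance(tr, c(0, 0), 0), "reference")
})

test_that("occupancy counts frames in the half-open window", {
  # whole 600-s track inside the near region
  tr <- synth_track(rep(0.1, 600 * 25))
  expect_equal(occupancy(tr, 1 / 3), 600)
  # alternating regions every frame: half the window
  tr2 <- synth_track(rep(c(0.1, 0.9), 300 * 25))
  expect_equal(occupancy(tr2, 1 / 3), 300)
  # the first-1-min window of a 10-min track uses exactly 1500 frames
  tr3 <- synth_track(rep(0.2, 600 * 25))
  expect_equal(occupancy(tr3, 1 / 3, window = c(0, 60)), 1500 / 25)
  expect_error(occupancy(tr3, window = c(10, 10)), "window")
  # far-third occupancy
  expect_equal(occupancy(tr2, 1 / 3, far = TRUE), 300)
})

test_that("the aversion index is the subtraction from the control mean", {
  res <- aversion_index(30, c(100, 120))
  expect_equal(res$index, -80)
  expect_equal(res$T_dw_mean, 110)
  # equal to the control mean: exactly zero
  expect_equal(aversion_index(110, c(100, 120))$index, 0)
  expect_error(aversion_index(30, numeric(0)), "control")
  # linearity: adding c seconds to T_odor shifts the index by exactly c
  base <- aversion_index(42, c(70, 95, 110))$index
  for (shift in c(1, 7.5, 120)) {
    expect_equal(aversion_index(42 + shift, c(70, 95, 110))$index,
                 base + shift)
  }
})

test_that("strong avoiders score negative indices against neutral controls", {
  controls <- vapply(1:5, function(s) {
    occupancy(gen_trajectory(behavior_spec(duration = 300, beta = 0,
                                           seed = 600 + s))$track, 1 / 3)
  }, numeric(1))
  # strong avoidance: a drift whose length scale spans the whole near third
  neg <- vapply(1:10, function(s) {
    t_odor <- occupancy(gen_trajectory(behavior_spec(duration = 300, beta = 5,
                                                     lambda_odor = 80,
                                                     seed = 700 + s))$track, 1 / 3)
    aversion_index(t_odor, controls)$index
  }, numeric(1))
  expect_gte(mean(neg < 0), 0.95)
})

test_that("raster membership is exhaustive and heat-map mass is conserved", {
  set.seed(8)
  tr <- gen_trajectory(behavior_spec(duration = 20, seed = 12))$track
  rd <- raster_data(tr)
  # every frame in exactly one of the two areas
  expect_true(all(rd$area %in% c("near", "rest")))
  expect_identical(nrow(rd), nrow(tr))
  # an always-near animal yields a single-colour raster
  rd2 <- raster_data(synth_track(rep(0.05, 100)))
  expect_identical(unique(as.character(rd2$area)), "near")
  # heat-map bin sums equal the number of valid frames
  hm <- position_heatmap(tr, bins = c(10, 8))
  expect_identical(sum(hm), sum(tr$valid))
})
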