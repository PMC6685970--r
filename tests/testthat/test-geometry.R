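test_that("polar ridge tracing recovers the mid-annulus radius", {
  ctr <- c(260, 260)
  img <- annulus_image(c(520, 520), ctr, 180, 220)
  path <- trace_centerline(img, scale = 1,
                           ref_ventral = c(ctr[1], ctr[2] + 200),
                           ref_dorsal = ctr + 200 * c(cos(5 * pi / 4),
                                                      sin(5 * pi / 4)),
                           threshold = 50)
  r <- sqrt((path$x - ctr[1])^2 + (path$y - ctr[2])^2)
  expect_lt(max(abs(r - 200)), 1)
  # arc length of the traced circle matches 2*pi*200 closely
  expect_lt(abs(path$perimeter_um - 2 * pi * 200) / (2 * pi * 200), 0.005)
})

test_that("tracing an elliptical band recovers the analytic mid-ellipse", {
  a <- 200; b <- 150; hw <- 18
  ctr <- c(250, 220)
  x <- matrix(rep(0:499, each = 440), 440, 500)
  y <- matrix(rep(0:439, 500), 440, 500)
  phi <- atan2(y - ctr[2], x - ctr[1])
  r_mid <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  img <- matrix(0, 440, 500); img[abs(r - r_mid) <= hw] <- 110
  path <- trace_centerline(img, scale = 1,
                           ref_ventral = c(ctr[1], ctr[2] + b),
                           ref_dorsal = ctr + c(-a, -b) / sqrt(2),
                           threshold = 50)
  phi_p <- atan2(path$y - ctr[2], path$x - ctr[1])
  r_exp <- a * b / sqrt((b * cos(phi_p))^2 + (a * sin(phi_p))^2)
  r_obs <- sqrt((path$x - ctr[1])^2 + (path$y - ctr[2])^2)
  expect_lt(max(abs(r_obs - r_exp)), 1)
})

test_that("a one-pixel ring traces to itself", {
  ctr <- c(150, 150)
  x <- matrix(rep(0:299, each = 300), 300, 300)
  y <- matrix(rep(0:299, 300), 300, 300)
  r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  img <- matrix(0, 300, 300); img[abs(r - 100) <= 0.5] <- 200
  path <- trace_centerline(img, scale = 1,
                           ref_ventral = c(ctr[1], ctr[2] + 100),
                           ref_dorsal = ctr + 100 * c(cos(5 * pi / 4),
                                                      sin(5 * pi / 4)),
                           threshold = 50)
  r_obs <- sqrt((path$x - ctr[1])^2 + (path$y - ctr[2])^2)
  expect_lt(max(abs(r_obs - 100)), 1)
})

test_that("straightening a straight horizontal path is an exact crop", {
  set.seed(2)
  img <- matrix(runif(120 * 200, 0, 255), 120, 200)
  path <- straight_path(20, 169, y = 60)
  strip <- straighten(img, path, half_width = 10)
  crop <- img[(60 - 10):(60 + 10) + 1, 20:169 + 1]
  expect_identical(unclass(strip)[, ], crop)
})

test_that("a nucleus at angle theta0 maps to its arc-length position", {
  ctr <- c(260, 260); R <- 200
  theta0 <- pi / 2 + 2.1          # measured from the ventral opening
  img <- annulus_image(c(520, 520), ctr, 180, 220)
  nuc <- ctr + R * c(cos(theta0), sin(theta0))
  img <- paint_discs(img, matrix(nuc, 1), r = 3, fg = 250)
  path <- trace_centerline(img, scale = 1,
                           ref_ventral = c(ctr[1], ctr[2] + R),
                           ref_dorsal = ctr + R * c(cos(5 * pi / 4),
                                                    sin(5 * pi / 4)),
                           threshold = 50)
  strip <- straighten(img, path, half_width = 20)
  w <- colSums(unclass(strip) > 200)          # the bright nucleus only
  x_obs <- sum((seq_along(w) - 1) * w) / sum(w)
  x_exp <- R * (theta0 - pi / 2)  # analytic polar arc length
  expect_lt(abs(x_obs - x_exp), 1.5)
})

test_that("straightening approximately conserves integrated intensity", {
  # smooth radial intensity profile across the band; Jacobian ~ 1 near the path
  ctr <- c(260, 260); R <- 200; hw <- 15
  x <- matrix(rep(0:519, each = 520), 520, 520)
  y <- matrix(rep(0:519, 520), 520, 520)
  r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  img <- matrix(0, 520, 520)
  inb <- abs(r - R) <= hw
  img[inb] <- 100 * exp(-((r[inb] - R) / 10)^2)
  path <- trace_centerline(1 * inb * 110, scale = 1,
                           ref_ventral = c(ctr[1], ctr[2] + R),
                           ref_dorsal = ctr + R * c(cos(5 * pi / 4),
                                                    sin(5 * pi / 4)),
                           threshold = 50)
  strip <- straighten(img, path, half_width = hw)
  expect_lt(abs(sum(strip) - sum(img)) / sum(img), 0.02)
})

test_that("sheet assembly aligns landmarks and pads with the NA sentinel", {
  mk <- function(len, lm) {
    structure(matrix(as.numeric(seq_len(5 * len)), 5, len), scale = 1,
              landmark_x = lm, class = c("unrolled_sheet", "matrix"))
  }
  sheets <- list(mk(100, 40), mk(120, 55), mk(110, 45))
  m <- assemble_map(sheets)
  # one aligned landmark column
  expect_identical(m$landmark_x, 55)
  expect_identical(m$shift_px, c(15, 0, 10))
  # width covers the longest shifted sheet; sentinel padding, values intact
  expect_equal(ncol(m$image), max(100 + 15, 120, 110 + 10))
  expect_identical(m$sheets[[1]][, 16:115], unclass(sheets[[1]])[, ])
  expect_true(all(is.na(m$sheets[[1]][, 1:15])))
  expect_error(assemble_map(sheets, section_index = c(2, 1, 3)), "increasing")
})

test_that("identical sheets assemble into identically aligned rows", {
  s <- structure(matrix(as.numeric(1:500), 5, 100), scale = 1, landmark_x = 30,
                 class = c("unrolled_sheet", "matrix"))
  m <- assemble_map(list(s, s, s))
  expect_identical(m$shift_px, c(0, 0, 0))
  expect_identical(m$sheets[[1]], m$sheets[[3]])
})

test_that("column counts are invariant to image resolution", {
  # the same physical section rendered at 1 and 0.5 um/px
  sp1 <- clean_section_spec(seed = 77)
  sp2 <- clean_section_spec(seed = 77)
  sp2$scale <- 0.5; sp2$nucleus_radius <- 12; sp2$size <- c(1720L, 1440L)
  sec1 <- gen_section(sp1); sec2 <- gen_section(sp2)
  # identical physical ground truth
  expect_equal(sec1$nuclei$s_um, sec2$nuclei$s_um, tolerance = 1e-10)
  p1 <- run_section_pipeline(sec1)
  p2 <- run_section_pipeline(sec2, size_range = c(120, 1040))
  n_cols <- nrow(sec1$expected_columns)
  c1 <- bin_columns(p1, n_columns = n_cols)
  c2 <- bin_columns(p2, n_columns = n_cols)
  expect_identical(c1$count, c2$count)
})
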