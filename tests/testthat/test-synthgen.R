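test_that("section generation is reproducible and respects lambda", {
  sp <- section_spec(a = 200, b = 160, lambda = 10, size = c(520, 440), seed = 5)
  s1 <- gen_section(sp)
  s2 <- gen_section(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$nuclei, s2$nuclei)

  # zero density: pure background, no nuclei
  s0 <- gen_section(section_spec(a = 200, b = 160, lambda = 0,
                                 size = c(520, 440), seed = 5))
  expect_identical(nrow(s0$nuclei), 0L)
  expect_lt(max(s0$image), s0$spec$fg_intensity)
})

test_that("total nucleus count follows the Poisson mean on a circle", {
  # circumference 2*pi*500 um at 20 per 100 um -> mean ~628.3
  expected <- 2 * pi * 500 / 100 * 20
  n_seeds <- 5
  totals <- vapply(seq_len(n_seeds), function(s) {
    sp <- section_spec(a = 500, b = 500, lambda = 20, size = c(1060, 1060),
                       seed = 100 + s)
    nrow(gen_section(sp)$nuclei)
  }, numeric(1))
  # sum of n_seeds independent Poisson draws: 3-sigma band
  expect_lt(abs(sum(totals) - n_seeds * expected),
            3 * sqrt(n_seeds * expected))
})

test_that("ground-truth nuclei are rendered and nothing else is", {
  sp <- clean_section_spec(seed = 31)
  sec <- gen_section(sp)
  # every listed centre sits on a rendered blob
  at_centres <- sec$image[cbind(round(sec$nuclei$y) + 1, round(sec$nuclei$x) + 1)]
  expect_true(all(at_centres == sp$fg_intensity))
  # no unlisted blob above the noise floor: blob count equals truth
  mask <- binarize(sec$image, 150)
  lab <- despeckle_and_split(mask, min_speck_area = 4)
  pts <- count_particles(lab, size_range = c(30, 260))
  expect_equal(nrow(pts), nrow(sec$nuclei))
})

test_that("band exceeding the image bounds is rejected", {
  sp <- section_spec(a = 400, b = 300, size = c(300, 300), seed = 1)
  expect_error(gen_section(sp), "bounds")
})

test_that("trajectories are seeded, bounded, and respond to drift", {
  sp <- behavior_spec(duration = 30, beta = 1, seed = 9)
  t1 <- gen_trajectory(sp)$track
  t2 <- gen_trajectory(sp)$track
  expect_identical(t1, t2)
  expect_true(all(t1$x >= 0 & t1$x <= sp$cage[1]))
  expect_true(all(t1$y >= 0 & t1$y <= sp$cage[2]))

  # strong repulsion, start far from the source: near third stays empty
  far <- gen_trajectory(behavior_spec(duration = 120, beta = 20,
                                      start = c(100, 300), seed = 2))
  expect_lt(occupancy(far$track, 1 / 3), 1)
})

test_that("an unbiased walk equidistributes over the cage", {
  # area fraction of the near-third region (numerical oracle on a fine grid)
  sp <- behavior_spec(beta = 0)
  gx <- seq(0.5, sp$cage[1] - 0.5, by = 1)
  gy <- seq(0.5, sp$cage[2] - 0.5, by = 1)
  d <- sqrt(outer((gy - sp$source[2])^2, (gx - sp$source[1])^2, "+"))
  area_frac <- mean(d / (sp$cage[2] - sp$source[2]) < 1 / 3)

  fracs <- vapply(1:12, function(s) {
    tr <- gen_trajectory(behavior_spec(duration = 900, beta = 0,
                                       seed = 400 + s))$track
    occupancy(tr, 1 / 3) / 900
  }, numeric(1))
  mc_err <- 3 * sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - area_frac), mc_err + 0.02)
})

test_that("count tables are Poisson with the group mean and reproducible", {
  cs <- count_spec(lambda = c(a = 0), sections_per_animal = 5,
                   animals_per_group = 2, seed = 3)
  expect_true(all(gen_counts(cs)$count == 0))

  cs30 <- count_spec(lambda = c(g = 30), sections_per_animal = 50,
                     animals_per_group = 2, seed = 8)
  tab <- gen_counts(cs30)
  expect_identical(tab, gen_counts(cs30))
  expect_lt(abs(mean(tab$count) - 30), 3 * sqrt(30 / nrow(tab)))
  expect_true(all(tab$count >= 0 & tab$count == round(tab$count)))
})
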