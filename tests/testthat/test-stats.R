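test_that("summary t-test agrees with the raw-sample t-test", {
  set.seed(2)
  for (rep in 1:10) {
    x1 <- rnorm(sample(3:8, 1), 10, 2)
    x2 <- rnorm(sample(3:8, 1), 12, 3)
    for (fl in c("welch", "pooled")) {
      raw <- ttest_raw(x1, x2, flavor = fl)
      smry <- ttest_from_summary(mean(x1), sd(x1) / sqrt(length(x1)), length(x1),
                                 mean(x2), sd(x2) / sqrt(length(x2)), length(x2),
                                 flavor = fl)
      expect_equal(raw$t, smry$t, tolerance = 1e-10)
      expect_equal(raw$df, smry$df, tolerance = 1e-10)
      expect_equal(raw$p, smry$p, tolerance = 1e-10)
    }
  }
})

test_that("degenerate and symmetric t-test cases behave", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  same <- ttest_raw(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # swapping groups flips t, keeps p
  a <- rnorm(5); b <- rnorm(5) + 1
  f <- ttest_raw(a, b); g <- ttest_raw(b, a)
  expect_equal(f$t, -g$t)
  expect_equal(f$p, g$p)
  expect_error(ttest_raw(1, c(1, 2)), "n >= 2")
  expect_error(ttest_from_summary(1, 0.1, 1, 2, 0.1, 3), "n >= 2")
  # identical summaries with zero sem: degenerate p = 1
  d <- ttest_from_summary(5, 0, 3, 5, 0, 3)
  expect_equal(d$p, 1)
})

test_that("a clear location shift is detected (permutation oracle)", {
  x1 <- c(1, 2, 3); x2 <- c(1, 2, 3) + 10
  res <- ttest_raw(x1, x2)
  # exact permutation test over all 20 arrangements of 6 values into two
  # groups of 3: the observed |mean difference| is the most extreme
  vals <- c(x1, x2)
  combs <- utils::combn(6, 3)
  diffs <- apply(combs, 2, function(idx) {
    abs(mean(vals[idx]) - mean(vals[-idx]))
  })
  p_perm <- mean(diffs >= abs(mean(x1) - mean(x2)))
  expect_equal(p_perm, 2 / 20)       # only the split and its mirror
  expect_lt(res$p, 0.01)             # t-test agrees in direction
})

test_that("BH adjustment equals the brute-force step-up definition", {
  # independent oracle: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
  bh_brute <- function(p) {
    m <- length(p)
    ord <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      js <- i:m
      q[ord[i]] <- min(1, min(p[ord[js]] * m / js))
    }
    q
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.04, 0.01)), c(0.04, 0.02))
  set.seed(9)
  for (rep in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  expect_error(bh_adjust(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("BH is permutation-invariant and never below the raw p", {
  set.seed(10)
  p <- runif(15)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  perm <- sample(15)
  expect_equal(bh_adjust(p[perm]), q[perm])
})

test_that("log2 normalization and pseudocount fold changes are exact", {
  expect_equal(log2_norm(100, 100), 0)
  expect_equal(log2_norm(400, 100), 2)
  expect_equal(log2_norm(50, 100), -1)
  # zero signal maps to the documented floor: half the smallest positive
  v <- log2_norm(c(0, 8, 400), 100)
  expect_equal(v[1], log2(4 / 100))
  expect_equal(log2_norm(0, 100, zero_floor = -10), -10)

  fc <- fold_change_pseudo(c(0, 0.9, 10), c(0, 0.4, 0))
  expect_equal(fc$fold_change, c(1, 2, 101))
  expect_equal(fc$log2_fc, log2(c(1, 2, 101)))
})

test_that("dorsal-ventral distribution bins 10 equal segments", {
  pos <- seq(0.05, 0.95, by = 0.1)
  expect_identical(dv_distribution(pos, 1), rep(1L, 10))
  # all at the dorsal origin
  expect_identical(dv_distribution(rep(0, 7), 1), c(7L, rep(0L, 9)))
  # the ventral end (position = length) closes the final bin
  expect_identical(dv_distribution(c(0.95, 1), 1)[10], 2L)
  # conservation
  set.seed(3)
  pos2 <- runif(123, 0, 5)
  expect_identical(sum(dv_distribution(pos2, 5)), 123L)
  expect_error(dv_distribution(c(-0.1, 0.5), 1))
})
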