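test_that("confusion counts tabulate voxels exactly", {
  p <- tiny_mask(c(1, 1, 0, 0), dim = c(2, 2, 1))
  t <- tiny_mask(c(1, 0, 1, 0), dim = c(2, 2, 1))
  cc <- confusion(p, t)
  expect_identical(unlist(cc[c("tp", "fp", "fn", "tn")]),
                   c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 4)
  expect_equal(dice(cc), 0.5)
  expect_equal(accuracy(cc), 0.5)
  expect_equal(precision(cc), 0.5)
  expect_equal(sensitivity(cc), 0.5)
  expect_equal(specificity(cc), 0.5)
})

test_that("perfect, inverted and empty predictions hit the closed-form values", {
  t <- tiny_mask(rep(c(1, 0), 16))
  same <- confusion(t, t)
  expect_equal(sapply(list(dice, accuracy, precision, sensitivity, specificity),
                      function(f) as.numeric(f(same))), rep(1, 5))
  inv <- confusion(tiny_mask(rep(c(0, 1), 16)), t)
  expect_equal(inv$tp, 0); expect_equal(inv$tn, 0)
  empty_pred <- confusion(tiny_mask(0), t)
  expect_equal(dice(empty_pred), 0)
  expect_equal(sensitivity(empty_pred), 0)
})

test_that("empty-vs-empty masks return flagged convention values", {
  cc <- confusion(tiny_mask(0), tiny_mask(0))
  for (f in list(dice, precision, sensitivity)) {
    val <- f(cc)
    expect_equal(as.numeric(val), 1)
    expect_true(isTRUE(attr(val, "degenerate")))
  }
  expect_equal(as.numeric(specificity(cc)), 1)
})

test_that("lesion_volume is voxel count times voxel size and additive", {
  m <- tiny_mask(c(rep(1, 10), rep(0, 22)))
  expect_equal(lesion_volume(m), 10)
  m$spacing <- c(0.43, 0.43, 4.6)
  expect_equal(lesion_volume(m), 10 * 0.43 * 0.43 * 4.6)
  expect_equal(lesion_volume(tiny_mask(0)), 0)
  # additivity over disjoint masks
  a <- array(0, c(4, 4, 2)); b <- array(0, c(4, 4, 2))
  a[1:5] <- 1; b[20:26] <- 1
  expect_equal(lesion_volume(tiny_mask(a + b)),
               lesion_volume(tiny_mask(a)) + lesion_volume(tiny_mask(b)))
})

test_that("metrics are invariant to axis permutation", {
  set.seed(5)
  p <- array(rbinom(60, 1, 0.4), c(3, 4, 5))
  t <- array(rbinom(60, 1, 0.4), c(3, 4, 5))
  base <- seg_metrics(p, t)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(seg_metrics(aperm(p, perm), aperm(t, perm)), base)
})

test_that("bland_altman matches closed forms", {
  x <- c(100, 200, 300, 400)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)
  expect_equal(as.numeric(same$r_squared), 1)

  shifted <- bland_altman(x + 100, x)
  expect_equal(shifted$bias, 100)
  expect_equal(shifted$loa_low, 100)   # SD of differences is 0
  expect_equal(shifted$loa_high, 100)
  expect_equal(as.numeric(shifted$r_squared), 1)
  expect_equal(shifted$plot_data$difference, rep(100, 4))
  expect_equal(shifted$plot_data$mean, x + 50)

  # noisy agreement over 50 cases: r^2 > 0.9 and bias within sampling bounds
  set.seed(6)
  manual <- runif(50, 500, 2000)
  sigma <- 30
  auto <- manual + rnorm(50, 0, sigma)
  ba <- bland_altman(auto, manual)
  expect_gt(as.numeric(ba$r_squared), 0.9)
  expect_lt(abs(ba$bias), 2 * sigma / sqrt(50) * 3)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  expect_error(bland_altman(1:3, 1:4), "lengths")
  expect_error(bland_altman(1, 1), "at least 2")
})
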