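test_that("anisotropic diffusion is conservative, edge-preserving and smooths noise", {
  cfg <- diffusion_config(iterations = 8, kappa = 0.1)
  const <- volume(array(3.7, c(16, 16, 2)))
  expect_equal(anisotropic_diffuse(const, cfg)$data, const$data)

  cs <- make_phantom(phantom_spec(seed = 6))
  out <- anisotropic_diffuse(cs$t1, cfg)
  # per-slice intensity sum conserved under replicated-edge flux
  for (k in c(1, 10, 20))
    expect_equal(sum(out$data[, , k]), sum(cs$t1$data[, , k]),
                 tolerance = 1e-6)
  # variance inside a homogeneous region strictly decreases
  inside <- cs$brain_truth$data == 1 & cs$lesion_truth$data == 0
  expect_lt(var(out$data[inside]), var(cs$t1$data[inside]))

  # total variation decreases monotonically per iteration on a 2D slice
  s <- cs$t1$data[, , 10]
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  v1 <- volume(array(s, c(64, 64, 1)))
  tvs <- numeric(4)
  for (i in 1:4) {
    v1 <- anisotropic_diffuse(v1, diffusion_config(iterations = 1, kappa = 0.1))
    tvs[i] <- tv(v1$data[, , 1])
  }
  expect_true(all(diff(c(tv(s), tvs)) < 0))

  expect_error(diffusion_config(dt = 0.3), "dt")
  expect_error(diffusion_config(iterations = 0), "iterations")
  expect_error(diffusion_config(kappa = -1), "kappa")
})

test_that("z-score normalization is slice-wise, exact and idempotent", {
  v <- volume(array(c(2, 4, 6, 8), c(2, 2, 1)))
  out <- zscore_normalize(v)
  expect_equal(out$data, array((c(2, 4, 6, 8) - 5) / sqrt(5), c(2, 2, 1)))
  expect_equal(mean(out$data), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(out$data^2)), 1, tolerance = 1e-12)
  # idempotence on already-normalized slices
  expect_equal(zscore_normalize(out)$data, out$data, tolerance = 1e-6)
  # constant slices become zeros with a warning, not an error
  vc <- volume(array(c(rep(5, 4), 1, 2, 3, 4), c(2, 2, 2)))
  expect_warning(outc <- zscore_normalize(vc), "constant")
  expect_equal(outc$data[, , 1], matrix(0, 2, 2))
})

test_that("min-max rescale maps the range onto [0,1] affinely", {
  v <- volume(array(c(2, 4, 6, 2, 4, 6, 2, 4), c(2, 2, 2)))
  out <- minmax_rescale(v)
  expect_equal(sort(unique(as.numeric(out$data))), c(0, 0.5, 1))
  expect_true(all(out$data >= 0 & out$data <= 1))
  expect_warning(z <- minmax_rescale(volume(array(1, c(2, 2, 2)))), "constant")
  expect_true(all(z$data == 0))
})

test_that("mask application zeroes exactly the voxels outside the mask", {
  cs <- make_phantom(phantom_spec(seed = 7))
  ones <- tiny_mask(1, dim = dim(cs$t1$data))
  expect_identical(apply_mask(cs$t1, ones)$data, cs$t1$data)
  zeros <- tiny_mask(0, dim = dim(cs$t1$data))
  expect_true(all(apply_mask(cs$t1, zeros)$data == 0))
  stripped <- apply_mask(cs$t1, cs$brain_truth)
  expect_true(all(stripped$data[cs$brain_truth$data == 0] == 0))
  expect_identical(stripped$data[cs$brain_truth$data == 1],
                   cs$t1$data[cs$brain_truth$data == 1])
  expect_error(apply_mask(cs$t1, tiny_mask(1)), "shapes")
})

test_that("bias field estimation recovers smooth multiplicative fields", {
  spec <- phantom_spec(seed = 8, noise_sigma = 0, bias_amplitude = 0,
                       misalign_max_shift = 0, misalign_max_theta = 0)
  flat <- make_phantom(spec)
  f0 <- estimate_bias_field(flat$t1, flat$brain_truth)
  idx <- flat$brain_truth$data == 1
  # bias-free phantom: field is 1 inside the mask
  expect_lt(max(abs(f0$data[idx] - 1)), 0.02)
  expect_equal(mean(f0$data[idx]), 1, tolerance = 1e-6)
  expect_true(min(f0$data) > 0)

  # injected linear ramp 0.8 -> 1.2 recovered at r > 0.95 inside the mask
  biased <- make_phantom(phantom_spec(seed = 8, bias_amplitude = 0.2))
  f1 <- estimate_bias_field(biased$t1, biased$brain_truth)
  idx <- biased$brain_truth$data == 1
  expect_gt(cor(f1$data[idx], biased$injected_bias$data[idx]), 0.95)

  expect_error(estimate_bias_field(flat$t1, tiny_mask(0, dim(flat$t1$data))),
               "empty")
})

test_that("bias correction divides out the field and reduces inhomogeneity", {
  cs <- make_phantom(phantom_spec(seed = 9, noise_sigma = 0))
  ones <- volume(array(1, dim(cs$t1$data)))
  expect_identical(correct_bias(cs$t1, ones)$data, cs$t1$data)
  bad <- volume(array(1, dim(cs$t1$data)))
  bad$data[1] <- -0.1
  expect_error(correct_bias(cs$t1, bad), "positive")

  f <- estimate_bias_field(cs$t1, cs$brain_truth)
  corrected <- correct_bias(cs$t1, f)
  # white-matter-analog region: coefficient of variation strictly decreases
  wm <- cs$brain_truth$data == 1 & cs$lesion_truth$data == 0
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(corrected$data[wm]), cv(cs$t1$data[wm]))
  # recovered clean intensities within 2% inside the region
  expect_lt(median(abs(corrected$data[wm] - 0.65)) / 0.65, 0.02)
})
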