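test_that("phantoms are bit-identical for a fixed seed", {
  spec <- phantom_spec(seed = 21)
  a <- make_phantom(spec); b <- make_phantom(spec)
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$flair$data, b$flair$data)
  expect_identical(a$lesion_truth$data, b$lesion_truth$data)
  expect_identical(unclass(a$injected_transform), unclass(b$injected_transform))
})

test_that("ground truth volume is the exact voxel count and lesions sit in the brain", {
  for (s in 21:25) {
    cs <- make_phantom(phantom_spec(seed = s))
    expect_identical(cs$true_lesion_volume_mm3,
                     sum(cs$lesion_truth$data) * prod(cs$lesion_truth$spacing))
    expect_true(all(cs$lesion_truth$data <= cs$brain_truth$data))
  }
  # zero-lesion spec gives an empty mask and zero volume
  none <- make_phantom(phantom_spec(seed = 1, lesion_count_range = c(0, 0)))
  expect_equal(sum(none$lesion_truth$data), 0)
  expect_equal(none$true_lesion_volume_mm3, 0)
})

test_that("a fixed-radius sphere voxelizes to the analytic count", {
  spec <- phantom_spec(seed = 31, dim = c(64, 64, 24),
                       brain_semiaxes = c(25, 21, 10.5),
                       lesion_count_range = c(1, 1),
                       lesion_radius_range = c(6.2, 6.2))
  cs <- make_phantom(spec)
  expect_equal(nrow(cs$lesions), 1)
  expect_equal(cs$lesions$r, 6.2)
  # independent oracle: enumerate voxel centres inside the analytic sphere
  co <- expand.grid(x = seq_len(64) - 0.5, y = seq_len(64) - 0.5,
                    z = seq_len(24) - 0.5)
  inside <- (co$x - cs$lesions$cx)^2 + (co$y - cs$lesions$cy)^2 +
    (co$z - cs$lesions$cz)^2 <= 6.2^2
  expect_equal(cs$true_lesion_volume_mm3, sum(inside))
  # close to the continuous sphere volume (4/3) * pi * r^3 ~ 998 mm^3
  expect_lt(abs(cs$true_lesion_volume_mm3 - 4 / 3 * pi * 6.2^3), 60)
})

test_that("modality contrast ordering holds before corruption", {
  spec <- phantom_spec(seed = 22, noise_sigma = 0, bias_amplitude = 0,
                       misalign_max_shift = 0, misalign_max_theta = 0)
  cs <- make_phantom(spec)
  les <- cs$lesion_truth$data == 1
  br <- cs$brain_truth$data == 1 & !les
  expect_gt(mean(cs$flair$data[les]), mean(cs$flair$data[br]))
  expect_lt(mean(cs$t1$data[les]), mean(cs$t1$data[br]))
  # skull shell is the brightest T1 structure and suppressed on FLAIR
  sk <- cs$t1$data > 0.9
  expect_gt(mean(cs$t1$data[sk]), mean(cs$t1$data[br]))
})

test_that("cohorts have distinct seeds and reproducible summaries", {
  cases <- make_dataset(6, phantom_spec(), seed = 77)
  expect_length(cases, 6)
  seeds <- vapply(cases, function(c) c$spec$seed, numeric(1))
  expect_identical(anyDuplicated(seeds), 0L)
  vols1 <- vapply(cases, `[[`, numeric(1), "true_lesion_volume_mm3")
  cases2 <- make_dataset(6, phantom_spec(), seed = 77)
  vols2 <- vapply(cases2, `[[`, numeric(1), "true_lesion_volume_mm3")
  expect_identical(vols1, vols2)
  expect_gt(length(unique(vols1)), 1)
})

test_that("impossible lesion placement errors out after bounded retries", {
  spec <- phantom_spec(seed = 1, brain_semiaxes = c(6, 6, 3),
                       lesion_radius_range = c(20, 20))
  expect_error(make_phantom(spec), "could not place")
})
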