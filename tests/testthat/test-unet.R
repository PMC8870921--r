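test_that("configuration validates shape divisibility and sizes", {
  expect_s3_class(unet_config(), "unet_config")
  expect_error(unet_config(depth = 5, in_shape = c(250, 250, 1)), "divisible")
  expect_error(unet_config(depth = 0), "depth")
  expect_error(unet_config(base_channels = 0), "base_channels")
})

test_that("closed-form parameter count matches the instantiated tensors", {
  for (cfg in list(unet_config(depth = 1, base_channels = 1, in_shape = c(8, 8, 1)),
                   unet_config(depth = 2, base_channels = 3, in_shape = c(16, 16, 1)),
                   unet_config(depth = 3, base_channels = 8, batch_norm = FALSE,
                               in_shape = c(64, 64, 1)))) {
    m <- build_unet(cfg, seed = 1)
    enumerated <- sum(vapply(m$params, function(p)
      sum(vapply(p, length, integer(1))), numeric(1)))
    expect_identical(count_parameters(cfg), enumerated)
  }
  # depth 1, base 1, no batch norm: hand arithmetic over the six convolutions
  cfg <- unet_config(depth = 1, base_channels = 1, batch_norm = FALSE,
                     in_shape = c(8, 8, 1))
  hand <- (9 * 1 + 1) * 1 + (9 * 1 + 1) * 1 +   # encoder conv a, b
    (9 * 1 + 1) * 2 + (9 * 2 + 1) * 2 +          # bottleneck a, b
    (9 * 2 + 1) * 1 + (9 * 2 + 1) * 1 + (9 * 1 + 1) * 1 +  # up, dec a, b
    (1 * 1 + 1) * 1                              # 1x1 head
  expect_identical(count_parameters(cfg), hand)
  # doubling base channels roughly quadruples the parameter count
  r <- count_parameters(unet_config(base_channels = 32)) /
    count_parameters(unet_config(base_channels = 16))
  expect_gt(r, 3.5); expect_lt(r, 4.2)
})

test_that("initialization is deterministic given the seed", {
  cfg <- unet_config(depth = 2, base_channels = 4, in_shape = c(16, 16, 1))
  m1 <- build_unet(cfg, seed = 33); m2 <- build_unet(cfg, seed = 33)
  expect_identical(m1$params, m2$params)
  m3 <- build_unet(cfg, seed = 34)
  expect_false(identical(m1$params, m3$params))
})

test_that("forward output is a membership map of the input shape", {
  cfg <- unet_config(depth = 3, base_channels = 2, in_shape = c(32, 32, 1))
  m <- build_unet(cfg, seed = 2)
  batch <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  p <- forward(m, batch)
  expect_identical(dim(p), dim(batch))
  expect_true(all(p > 0 & p < 1))
  # bottleneck spatial size is side / 2^depth (forward would fail otherwise)
  expect_equal(32 / 2^cfg$depth, 4)
  # eval-mode purity: duplicated slices give identical outputs
  dup <- array(batch[, , c(1, 1)], c(32, 32, 2))
  pd <- forward(m, dup)
  expect_identical(pd[, , 1], pd[, , 2])
  expect_error(forward(m, array(0, c(16, 16, 1))), "match")
})

test_that("analytic gradients agree with central differences", {
  cfg <- unet_config(depth = 2, base_channels = 2, in_shape = c(8, 8, 1))
  m <- build_unet(cfg, seed = 2)
  set.seed(7)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- as.numeric(array(rbinom(8 * 8 * 3, 1, 0.3), c(8, 8, 3)))
  X <- matrix(as.numeric(x), ncol = 1)
  st0 <- m$state
  loss_at <- function() {
    fw <- lesionquant:::unet_forward_mat(m, X, 3, training = TRUE)
    bce_loss(as.numeric(fw$prob), y)
  }
  fw <- lesionquant:::unet_forward_mat(m, X, 3, training = TRUE)
  p <- as.numeric(fw$prob)
  grads <- lesionquant:::unet_backward_mat(m, fw$caches,
                                           matrix((p - y) / length(y), ncol = 1))
  eps <- 1e-6
  for (nm in c("enc1a", "enc2b", "botb", "up1", "dec2a", "head")) {
    for (f in names(m$params[[nm]])) {
      i <- sample(length(m$params[[nm]][[f]]), 1)
      orig <- m$params[[nm]][[f]][i]
      m$params[[nm]][[f]][i] <- orig + eps; m$state <- st0; lp <- loss_at()
      m$params[[nm]][[f]][i] <- orig - eps; m$state <- st0; lm <- loss_at()
      m$params[[nm]][[f]][i] <- orig; m$state <- st0
      gn <- (lp - lm) / (2 * eps); ga <- grads[[nm]][[f]][i]
      if (abs(gn) + abs(ga) > 1e-8)
        expect_lt(abs(gn - ga) / (abs(gn) + abs(ga)), 1e-4)
    }
  }
})

test_that("checkpoints round-trip the model exactly", {
  cfg <- unet_config(depth = 2, base_channels = 2, in_shape = c(16, 16, 1))
  m <- build_unet(cfg, seed = 5)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(unclass(m2$cfg), unclass(m$cfg))
  batch <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  expect_identical(forward(m, batch), forward(m2, batch))
})
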