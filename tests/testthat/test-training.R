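test_that("binary cross-entropy matches its closed forms", {
  eps <- 1e-7
  y <- c(1, 0, 1, 0)
  expect_lt(bce_loss(c(1 - eps, eps, 1 - eps, eps), y), 1e-6)
  # uniform 0.5 prediction costs ln 2 regardless of the target
  expect_equal(bce_loss(rep(0.5, 4), y), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(rep(0.5, 4), rep(1, 4)), log(2), tolerance = 1e-12)
  # moving any single prediction toward its target lowers the loss
  p <- c(0.6, 0.4, 0.7, 0.2)
  p2 <- p; p2[1] <- 0.8
  expect_lt(bce_loss(p2, y), bce_loss(p, y))
  expect_error(bce_loss(c(0.5, 0.5), y), "shapes")
})

test_that("training runs to completion with a full epoch log and is seeded", {
  set.seed(8)
  # trivially separable slices: bright square on dark background
  n <- 6
  x <- array(0.1, c(16, 16, n)); y <- array(0, c(16, 16, n))
  for (i in seq_len(n)) {
    r <- 4:9 + (i %% 3)
    x[r, r, i] <- 0.9; y[r, r, i] <- 1
  }
  cfg <- unet_config(depth = 2, base_channels = 2, in_shape = c(16, 16, 1))
  tc <- training_config(epochs = 5, batch_size = 4, seed = 13)
  f1 <- train_model(build_unet(cfg, seed = 13), list(x = x, y = y), tc,
                    validation = list(x = x, y = y))
  expect_identical(nrow(f1$log), 5L)
  expect_true(all(c("train_loss", "train_dice", "val_dice",
                    "val_specificity") %in% names(f1$log)))
  expect_true(all(f1$log$train_dice >= 0 & f1$log$train_dice <= 1))
  # identical seed, identical trajectory
  f2 <- train_model(build_unet(cfg, seed = 13), list(x = x, y = y), tc)
  expect_equal(f1$log$train_loss, f2$log$train_loss, tolerance = 1e-12)
  # loss goes down on a separable problem
  expect_lt(tail(f1$log$train_loss, 1), f1$log$train_loss[1])
  expect_error(train_model(build_unet(cfg, 1), list(x = x, y = x), tc),
               "binary")
})

test_that("cross-validation draws disjoint subject-level splits", {
  set.seed(9)
  subjects <- lapply(1:6, function(i) {
    x <- array(0.1, c(16, 16, 2)); y <- array(0, c(16, 16, 2))
    x[5:10, 5:10, ] <- 0.9; y[5:10, 5:10, ] <- 1
    list(x = x, y = y)
  })
  cv <- crossval(subjects,
                 unet_config(depth = 1, base_channels = 1,
                             in_shape = c(16, 16, 1)),
                 training_config(epochs = 1, batch_size = 8, repeats = 10,
                                 seed = 3))
  expect_identical(nrow(cv$per_repeat), 10L)
  expect_true(all(cv$per_repeat$n_train == 5))
  expect_true(all(cv$per_repeat$n_val == 1))
  expect_named(cv$mean, c("dice", "accuracy", "precision", "sensitivity",
                          "specificity"))
  expect_error(crossval(subjects[1:3],
                        unet_config(depth = 1, base_channels = 1,
                                    in_shape = c(16, 16, 1)),
                        training_config()), ">= 5")
})

test_that("training data preparation yields aligned model-ready pairs", {
  cases <- cv_cohort()[1:2]
  pcfg <- test_pipeline_config()
  brain <- prepare_training_data(cases, "brain", pcfg)
  lesion <- prepare_training_data(cases, "lesion", pcfg)
  for (s in c(brain, lesion)) {
    expect_identical(dim(s$x), c(64L, 64L, 20L))
    expect_identical(dim(s$y), c(64L, 64L, 20L))
    expect_true(all(s$x >= 0 & s$x <= 1))
    expect_true(all(s$y %in% c(0, 1)))
  }
  # lesion inputs are skull-stripped: nothing outside the true brain mask
  expect_true(all(lesion[[1]]$x[cases[[1]]$brain_truth$data == 0] == 0))
  # the FLAIR lesion signal survives preprocessing: hyperintense vs brain
  x <- lesion[[1]]$x; y <- lesion[[1]]$y
  expect_gt(mean(x[y == 1]), mean(x[y == 0 & x > 0.1]))
})
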