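# Shared fixtures, built once per test run and memoized. Training the two
# networks is the expensive part; the end-to-end and degenerate-input tests
# reuse the same pair of trained models.

.lq_test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.lq_test_cache[[key]])) .lq_test_cache[[key]] <- force(expr)
  .lq_test_cache[[key]]
}

test_pipeline_config <- function() {
  pipeline_config(model_shape = c(64, 64))
}

test_unet_config <- function(base_channels = 4) {
  unet_config(depth = 3, base_channels = base_channels,
              in_shape = c(64, 64, 1))
}

# cohorts: training (16 cases), cross-validation (10), held-out test (10)
train_cohort <- function() memo("train_cohort",
                                make_dataset(16, phantom_spec(), seed = 101))
cv_cohort <- function() memo("cv_cohort",
                             make_dataset(10, phantom_spec(), seed = 42))
heldout_cohort <- function() memo("heldout_cohort",
                                  make_dataset(10, phantom_spec(), seed = 202))

bind_subjects <- function(subjects) {
  d <- dim(subjects[[1]]$x)
  n <- sum(vapply(subjects, function(s) dim(s$x)[3], numeric(1)))
  list(x = array(unlist(lapply(subjects, `[[`, "x"), use.names = FALSE),
                 c(d[1:2], n)),
       y = array(unlist(lapply(subjects, `[[`, "y"), use.names = FALSE),
                 c(d[1:2], n)))
}

# the "final" models used by the end-to-end and degenerate-input checks:
# trained once on the 16-case cohort with the protocol loss and optimizer
final_models <- function() memo("final_models", {
  pcfg <- test_pipeline_config()
  models <- list()
  for (target in c("brain", "lesion")) {
    subjects <- prepare_training_data(train_cohort(), target, pcfg)
    m <- build_unet(test_unet_config(), seed = 9)
    epochs <- if (target == "brain") 15 else 40
    fit <- train_model(m, bind_subjects(subjects),
                       training_config(epochs = epochs, seed = 9))
    models[[target]] <- fit$model
  }
  models
})

# small flat binary volume for quick mask tests
tiny_mask <- function(values, dim = c(4, 4, 2), spacing = c(1, 1, 1)) {
  as_binary_mask(volume(array(values, dim), spacing))
}
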