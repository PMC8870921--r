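#' Training protocol configuration
#'
#' Defaults follow the training protocol used for both networks: binary
#' cross-entropy loss, Adam with learning rate 0.001, batch size 32, 60
#' epochs, and repeated random 80:20 train/validation splits (10 repeats).
#'
#' @param batch_size Slices per optimization step (default 32).
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs Training epochs (default 60).
#' @param split Train fraction of each cross-validation split (default 0.8).
#' @param repeats Number of seeded random splits (default 10).
#' @param threshold Binarization threshold for metrics logged during training
#'   (default 0.5).
#' @param seed Seed controlling shuffling (and split draws in [crossval()]).
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 32, learning_rate = 0.001,
                            epochs = 60, split = 0.8, repeats = 10,
                            threshold = 0.5, seed = 1L) {
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), split = split,
                 repeats = as.integer(repeats), threshold = threshold,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Binary cross-entropy loss
#'
#' Mean over voxels of `-(y log p + (1-y) log(1-p))`, with predictions
#' clipped away from 0 and 1.
#'
#' @param pred Numeric predictions in `[0, 1]`.
#' @param target Binary targets of the same shape.
#' @param eps Clipping bound (default `1e-7`).
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (length(pred) != length(target)) stop("pred and target shapes differ")
  p <- pmin(pmax(as.numeric(pred), eps), 1 - eps)
  y <- as.numeric(target)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) lapply(p, function(q)
    list(m = array(0, dim(q) %||% length(q)), v = array(0, dim(q) %||% length(q)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    for (f in names(params[[nm]])) {
      g <- grads[[nm]][[f]]
      if (is.null(g)) next
      st <- opt[[nm]][[f]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      opt[[nm]][[f]] <- st
    }
  }
  list(params = params, opt = opt)
}

## ---- training loop --------------------------------------------------------

eval_in_chunks <- function(m, x, chunk = 32L) {
  d <- dim(x)
  out <- array(0, d)
  for (s in split(seq_len(d[3]), ceiling(seq_len(d[3]) / chunk)))
    out[, , s] <- forward(m, x[, , s, drop = FALSE])
  out
}

#' Train a U-Net on paired slices and masks
#'
#' Mini-batch training with Adam on binary cross-entropy. All slices are
#' visited each epoch in a seed-controlled shuffled order. Per-epoch loss and
#' the five segmentation measures (computed by the metrics module on
#' predictions binarized at `cfg$threshold`) are logged for the training set
#' and, when given, a validation set.
#'
#' @param m A `unet_model` (modified in place and returned).
#' @param data List with `x` (slices, `rows x cols x n` array) and `y`
#'   (matching binary masks).
#' @param cfg A [training_config()].
#' @param validation Optional list with `x` and `y` for held-out evaluation.
#' @param verbose Print per-epoch progress.
#' @return List with `model` and `log` (data frame, one row per epoch:
#'   loss/Dice/accuracy/precision/sensitivity/specificity for train and,
#'   when available, validation).
#' @export
train_model <- function(m, data, cfg = training_config(), validation = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(m, "unet_model"), inherits(cfg, "training_config"))
  x <- data$x; y <- data$y
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(y)) == 2L) dim(y) <- c(dim(y), 1L)
  n <- dim(x)[3]
  if (is.null(n) || n < 1L) stop("empty dataset")
  if (!identical(dim(x), dim(y))) stop("slices and masks shapes differ")
  if (!is_binary_data(y)) stop("targets must be binary")

  if (is.null(m$opt)) m$opt <- adam_init(m$params)
  if (is.null(m$step)) m$step <- 0L
  # fresh model: start the head bias at the empirical foreground log-odds,
  # so rare-class BCE skips the long plateau where everything is background
  if (m$step == 0L && all(m$params$head$b == 0)) {
    pos <- min(max(mean(y), 1e-4), 1 - 1e-4)
    m$params$head$b <- stats::qlogis(pos)
  }
  H <- m$cfg$in_shape[1]; W <- m$cfg$in_shape[2]
  log_rows <- vector("list", cfg$epochs)

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0; cc <- c(tp = 0, fp = 0, fn = 0, tn = 0)
      for (b in batches) {
        Xb <- matrix(as.numeric(x[, , b]), ncol = 1L)
        Yb <- as.numeric(y[, , b])
        fw <- unet_forward_mat(m, Xb, length(b), training = TRUE)
        p <- as.numeric(fw$prob)
        loss <- bce_loss(p, Yb)
        if (!is.finite(loss))
          stop("NaN/Inf loss at epoch ", ep, "; lower the learning rate")
        # d(mean BCE)/d(logits) for a sigmoid head
        dlogits <- matrix((p - Yb) / length(Yb), ncol = 1L)
        grads <- unet_backward_mat(m, fw$caches, dlogits)
        m$step <- m$step + 1L
        upd <- adam_step(m$params, grads, m$opt, cfg$learning_rate, m$step)
        m$params <- upd$params; m$opt <- upd$opt
        ep_loss <- ep_loss + loss * length(b)
        pb <- as.numeric(p >= cfg$threshold)
        cc <- cc + c(tp = sum(pb == 1 & Yb == 1), fp = sum(pb == 1 & Yb == 0),
                     fn = sum(pb == 0 & Yb == 1), tn = sum(pb == 0 & Yb == 0))
      }
      ccl <- structure(as.list(cc), class = "confusion_counts")
      names(ccl) <- c("tp", "fp", "fn", "tn")
      row <- data.frame(epoch = ep, train_loss = ep_loss / n,
                        train_dice = as.numeric(dice(ccl)),
                        train_accuracy = as.numeric(accuracy(ccl)),
                        train_precision = as.numeric(precision(ccl)),
                        train_sensitivity = as.numeric(sensitivity(ccl)),
                        train_specificity = as.numeric(specificity(ccl)))
      if (!is.null(validation)) {
        vp <- eval_in_chunks(m, validation$x)
        vm <- seg_metrics(array(as.numeric(vp >= cfg$threshold), dim(vp)),
                          validation$y)
        row$val_loss <- bce_loss(vp, validation$y)
        row$val_dice <- vm[["dice"]]
        row$val_accuracy <- vm[["accuracy"]]
        row$val_precision <- vm[["precision"]]
        row$val_sensitivity <- vm[["sensitivity"]]
        row$val_specificity <- vm[["specificity"]]
      }
      log_rows[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  dice %.4f%s", ep,
                        row$train_loss, row$train_dice,
                        if (!is.null(validation))
                          sprintf("  val_dice %.4f", row$val_dice) else ""))
    }
  })
  list(model = m, log = do.call(rbind, log_rows))
}

#' Repeated 80:20 cross-validation
#'
#' For each of `cfg$repeats` seeded random splits, holds out `1 - cfg$split`
#' of the subjects (splits are at the subject level, never the slice level,
#' to avoid leakage), trains a fresh model on the rest, and evaluates the
#' five segmentation measures on the held-out subjects.
#'
#' @param data List of subjects, each a list with slice array `x` and mask
#'   array `y` (as produced by [prepare_training_data()]).
#' @param unet_cfg A [unet_config()] for the per-repeat models.
#' @param train_cfg A [training_config()]; its `seed` drives split draws,
#'   model initialization and shuffling.
#' @param verbose Print per-repeat progress.
#' @return List with `per_repeat` (data frame of validation metrics, one row
#'   per repeat) and `mean` (named vector of their means).
#' @export
crossval <- function(data, unet_cfg, train_cfg = training_config(),
                     verbose = FALSE) {
  n <- length(data)
  if (n < 5L) stop("need >= 5 subjects so a 20% validation split is non-empty")
  n_train <- max(1L, min(n - 1L, round(train_cfg$split * n)))
  rows <- vector("list", train_cfg$repeats)
  for (r in seq_len(train_cfg$repeats)) {
    rseed <- (train_cfg$seed * 131 + r * 977) %% 2147483647
    idx_train <- with_seed(rseed, sample.int(n, n_train))
    idx_val <- setdiff(seq_len(n), idx_train)
    stopifnot(length(intersect(idx_train, idx_val)) == 0L)
    bind <- function(ix) list(
      x = array(unlist(lapply(data[ix], function(s) s$x), use.names = FALSE),
                c(dim(data[[ix[1]]]$x)[1:2],
                  sum(vapply(data[ix], function(s) dim(s$x)[3], numeric(1))))),
      y = array(unlist(lapply(data[ix], function(s) s$y), use.names = FALSE),
                c(dim(data[[ix[1]]]$y)[1:2],
                  sum(vapply(data[ix], function(s) dim(s$y)[3], numeric(1))))))
    tr <- bind(idx_train); va <- bind(idx_val)
    m <- build_unet(unet_cfg, seed = rseed)
    cfg_r <- train_cfg; cfg_r$seed <- as.integer(rseed)
    fit <- train_model(m, tr, cfg_r)
    vp <- eval_in_chunks(fit$model, va$x)
    vm <- seg_metrics(array(as.numeric(vp >= train_cfg$threshold), dim(vp)),
                      va$y)
    rows[[r]] <- data.frame(repeat_id = r, n_train = length(idx_train),
                            n_val = length(idx_val), t(vm))
    if (verbose)
      message(sprintf("repeat %d/%d: val dice %.4f", r, train_cfg$repeats,
                      vm[["dice"]]))
  }
  per_repeat <- do.call(rbind, rows)
  metric_cols <- c("dice", "accuracy", "precision", "sensitivity", "specificity")
  list(per_repeat = per_repeat, mean = colMeans(per_repeat[metric_cols]))
}
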