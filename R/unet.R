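#' U-Net architecture configuration
#'
#' One configurable 2D encoder-decoder serves both tasks: brain extraction on
#' T1-w slices and lesion segmentation on skull-stripped FLAIR slices. Encoder
#' blocks are two 3x3 same-padded convolutions (each followed by optional
#' batch normalization and ReLU) and a 2x2 stride-2 max-pool; decoder blocks
#' are 2x nearest-neighbour up-sampling, a 3x3 convolution, concatenation with
#' the matching encoder feature map, and two further 3x3 convolutions; the
#' head is a 1x1 convolution with a sigmoid, giving per-pixel membership.
#'
#' @param depth Number of pooling levels (default 5).
#' @param base_channels Feature maps at the first level (default 16), doubled
#'   at each deeper level.
#' @param batch_norm Use batch normalization after every 3x3 convolution
#'   (default `TRUE`).
#' @param in_shape Input slice shape `(rows, cols, channels)`; the spatial
#'   sides must be divisible by `2^depth`.
#' @return A `unet_config` list.
#' @export
unet_config <- function(depth = 5, base_channels = 16, batch_norm = TRUE,
                        in_shape = c(256, 256, 1)) {
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  if (depth < 1L) stop("depth must be >= 1")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (length(in_shape) != 3L) stop("in_shape must be (rows, cols, channels)")
  if (any(in_shape[1:2] %% 2^depth != 0))
    stop(sprintf("input sides %dx%d not divisible by 2^depth = %d",
                 in_shape[1], in_shape[2], 2^depth))
  structure(list(depth = depth, base_channels = base_channels,
                 batch_norm = isTRUE(batch_norm),
                 in_shape = as.integer(in_shape)),
            class = "unet_config")
}

# channel schedule: encoder levels, bottleneck, decoder levels
unet_channels <- function(cfg) {
  enc <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1L)
  list(enc = enc, bottleneck = cfg$base_channels * 2^cfg$depth)
}

## ---- index-map caches -----------------------------------------------------
## Activations live as (H*W*N) x C matrices (row = pixel of a batch slice).
## Spatial ops become row-index gathers; the index vectors depend only on the
## (H, W, N) shape and are cached per shape.

.lq_maps <- new.env(parent = emptyenv())

grid_rows <- function(H, W, N) {
  list(h = rep_len(rep(seq_len(H), times = W), H * W * N),
       w = rep_len(rep(seq_len(W), each = H), H * W * N),
       n = rep(seq_len(N), each = H * W))
}

# 2x2 stride-2 max-pool: four gather maps from the pooled grid into the input
pool_maps <- function(H, W, N) {
  key <- paste0("p", H, "x", W, "x", N)
  if (!is.null(.lq_maps[[key]])) return(.lq_maps[[key]])
  g <- grid_rows(H %/% 2L, W %/% 2L, N)
  maps <- vector("list", 4L)
  k <- 0L
  for (b in 0:1) for (a in 0:1) {
    k <- k + 1L
    maps[[k]] <- (2L * g$h - 1L + a) + H * (2L * g$w - 2L + b) +
      H * W * (g$n - 1L)
  }
  .lq_maps[[key]] <- maps
  maps
}

# 2x nearest-neighbour up-sampling: map from output rows to input rows
up_map <- function(H, W, N) {
  key <- paste0("u", H, "x", W, "x", N)
  if (!is.null(.lq_maps[[key]])) return(.lq_maps[[key]])
  g <- grid_rows(2L * H, 2L * W, N)
  .lq_maps[[key]] <- ((g$h + 1L) %/% 2L) + H * ((g$w + 1L) %/% 2L - 1L) +
    H * W * (g$n - 1L)
  .lq_maps[[key]]
}

## ---- primitive layers (forward + backward) --------------------------------

conv_fwd <- function(X, W, b, shape) {
  cin <- dim(W)[3]; cout <- dim(W)[4]
  if (dim(W)[1] == 1L) {
    out <- cpp_colaffine(X %*% matrix(W, cin, cout), rep(1, cout), b)
  } else {
    out <- cpp_conv3_fwd(X, as.numeric(W), b, shape[1], shape[2], shape[3],
                         cout)
  }
  out
}

conv_bwd <- function(dOut, X, W, shape) {
  cin <- dim(W)[3]; cout <- dim(W)[4]
  db <- colSums(dOut)
  if (dim(W)[1] == 1L) {
    dW <- array(crossprod(X, dOut), dim(W))
    dX <- dOut %*% t(matrix(W, cin, cout))
  } else {
    dW <- array(cpp_conv3_dw(X, dOut, shape[1], shape[2], shape[3]), dim(W))
    dX <- cpp_conv3_dx(dOut, as.numeric(W), shape[1], shape[2], shape[3], cin)
  }
  list(dX = dX, dW = dW, db = db)
}

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    vv <- colMeans(X * X) - mu^2
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * vv
  } else {
    mu <- run_mean; vv <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  invstd <- 1 / sqrt(pmax(vv, 0) + eps)
  xhat <- cpp_colaffine(X, invstd, -mu * invstd)
  out <- cpp_colaffine(xhat, gamma, beta)
  list(out = out, xhat = xhat, invstd = invstd,
       new_mean = new_mean, new_var = new_var)
}

bn_bwd <- function(dOut, cache, gamma) {
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- cpp_colaffine(dOut, gamma, numeric(length(gamma)))
  m2 <- colMeans(dxhat * cache$xhat)
  m1 <- colMeans(dxhat)
  dX <- cpp_colaffine(dxhat - cpp_colaffine(cache$xhat, m2, m1),
                      cache$invstd, numeric(length(gamma)))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(X, shape) {
  maps <- pool_maps(shape[1], shape[2], shape[3])
  out <- X[maps[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(out), ncol(out))
  for (k in 2:4) {
    Xk <- X[maps[[k]], , drop = FALSE]
    m <- Xk > out
    out[m] <- Xk[m]
    arg[m] <- k
  }
  list(out = out, arg = arg)
}

pool_bwd <- function(dOut, arg, shape, n_in_rows, cols) {
  maps <- pool_maps(shape[1], shape[2], shape[3])
  dX <- matrix(0, n_in_rows, cols)
  for (k in 1:4) {
    contrib <- dOut * (arg == k)
    idx <- maps[[k]]
    dX[idx, ] <- dX[idx, , drop = FALSE] + contrib
  }
  dX
}

up_fwd <- function(X, shape) {
  X[up_map(shape[1], shape[2], shape[3]), , drop = FALSE]
}

up_bwd <- function(dOut, shape) {
  g <- up_map(shape[1], shape[2], shape[3])
  unname(rowsum(dOut, g))   # groups 1..R_in, sorted ascending
}

relu_fwd <- function(X) {
  m <- X > 0
  list(out = X * m, mask = m)
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

## ---- model construction ---------------------------------------------------

new_conv_params <- function(k, cin, cout, bn) {
  p <- list(W = he_init(k, cin, cout), b = numeric(cout))
  if (bn) {
    p$gamma <- rep(1, cout); p$beta <- numeric(cout)
  }
  p
}

#' Build a U-Net model
#'
#' Parameters are initialized deterministically from `seed` (He-scaled normal
#' weights, zero biases, unit batch-norm gains).
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed controlling initialization.
#' @return A `unet_model` handle: an environment holding `cfg`, the parameter
#'   list, batch-norm running statistics, and the parameter count.
#' @export
build_unet <- function(cfg = unet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- unet_channels(cfg)
  bn <- cfg$batch_norm
  with_seed(seed, {
    params <- list()
    state <- list()
    add_conv <- function(name, k, cin, cout) {
      params[[name]] <<- new_conv_params(k, cin, cout, bn && k == 3L)
      if (bn && k == 3L)
        state[[name]] <<- list(mean = numeric(cout), var = rep(1, cout))
    }
    cin <- cfg$in_shape[3]
    for (i in seq_len(cfg$depth)) {
      add_conv(paste0("enc", i, "a"), 3L, cin, ch$enc[i])
      add_conv(paste0("enc", i, "b"), 3L, ch$enc[i], ch$enc[i])
      cin <- ch$enc[i]
    }
    add_conv("bota", 3L, cin, ch$bottleneck)
    add_conv("botb", 3L, ch$bottleneck, ch$bottleneck)
    cin <- ch$bottleneck
    for (i in rev(seq_len(cfg$depth))) {
      add_conv(paste0("up", i), 3L, cin, ch$enc[i])
      add_conv(paste0("dec", i, "a"), 3L, 2L * ch$enc[i], ch$enc[i])
      add_conv(paste0("dec", i, "b"), 3L, ch$enc[i], ch$enc[i])
      cin <- ch$enc[i]
    }
    add_conv("head", 1L, ch$enc[1], 1L)
    m <- new.env(parent = emptyenv())
    m$cfg <- cfg
    m$params <- params
    m$state <- state
    m$n_parameters <- sum(vapply(params, function(p)
      sum(vapply(p, length, integer(1))), numeric(1)))
    class(m) <- "unet_model"
    m
  })
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model depth %d, base %d, batch_norm %s, %s parameters>\n",
              x$cfg$depth, x$cfg$base_channels, x$cfg$batch_norm,
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

#' Closed-form parameter count of a U-Net configuration
#'
#' Each k x k convolution holds `(k^2 * c_in + 1) * c_out` weights and biases,
#' plus `2 * c_out` batch-norm gain/shift parameters when enabled (running
#' statistics are state, not parameters). Matches the instantiated model
#' exactly.
#'
#' @param cfg A [unet_config()].
#' @return Integer-valued parameter total.
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- unet_channels(cfg)
  bn2 <- if (cfg$batch_norm) 2 else 0
  conv3 <- function(cin, cout) (9 * cin + 1) * cout + bn2 * cout
  total <- 0
  cin <- cfg$in_shape[3]
  for (i in seq_len(cfg$depth)) {
    total <- total + conv3(cin, ch$enc[i]) + conv3(ch$enc[i], ch$enc[i])
    cin <- ch$enc[i]
  }
  total <- total + conv3(cin, ch$bottleneck) + conv3(ch$bottleneck, ch$bottleneck)
  cin <- ch$bottleneck
  for (i in rev(seq_len(cfg$depth))) {
    total <- total + conv3(cin, ch$enc[i]) + conv3(2 * ch$enc[i], ch$enc[i]) +
      conv3(ch$enc[i], ch$enc[i])
    cin <- ch$enc[i]
  }
  total + (1 * ch$enc[1] + 1) * 1
}

## ---- forward / backward ---------------------------------------------------

# one conv(+BN)+ReLU unit; returns output and everything backward needs
unit_fwd <- function(m, name, X, shape, training) {
  p <- m$params[[name]]
  z <- conv_fwd(X, p$W, p$b, shape)
  cache <- list(X = X, shape = shape)
  if (!is.null(p$gamma)) {
    st <- m$state[[name]]
    bn <- bn_fwd(z, p$gamma, p$beta, st$mean, st$var, training)
    if (training) m$state[[name]] <- list(mean = bn$new_mean, var = bn$new_var)
    cache$bn <- bn[c("xhat", "invstd")]
    z <- bn$out
  }
  r <- relu_fwd(z)
  cache$mask <- r$mask
  list(out = r$out, cache = cache)
}

unit_bwd <- function(m, name, dOut, cache, grads) {
  p <- m$params[[name]]
  dz <- dOut * cache$mask
  if (!is.null(p$gamma)) {
    bb <- bn_bwd(dz, cache$bn, p$gamma)
    grads[[name]]$gamma <- bb$dgamma
    grads[[name]]$beta <- bb$dbeta
    dz <- bb$dX
  }
  cb <- conv_bwd(dz, cache$X, p$W, cache$shape)
  grads[[name]]$W <- cb$dW
  grads[[name]]$b <- cb$db
  list(dX = cb$dX, grads = grads)
}

# Full U-Net forward on a batch. X: (H*W*N) x C_in matrix; returns sigmoid
# memberships plus (when training) the cache needed for the backward pass.
unet_forward_mat <- function(m, X, N, training = FALSE, want_cache = training) {
  cfg <- m$cfg
  H <- cfg$in_shape[1]; W <- cfg$in_shape[2]
  shape <- c(H, W, N)
  caches <- if (want_cache) list() else NULL
  skips <- list(); skip_shapes <- list()
  for (i in seq_len(cfg$depth)) {
    for (u in c("a", "b")) {
      nm <- paste0("enc", i, u)
      r <- unit_fwd(m, nm, X, shape, training)
      if (want_cache) caches[[nm]] <- r$cache
      X <- r$out
    }
    skips[[i]] <- X; skip_shapes[[i]] <- shape
    pr <- pool_fwd(X, shape)
    if (want_cache) caches[[paste0("pool", i)]] <-
      list(arg = pr$arg, shape = shape, n_in = nrow(X))
    X <- pr$out
    shape <- c(shape[1] %/% 2L, shape[2] %/% 2L, N)
  }
  for (u in c("a", "b")) {
    nm <- paste0("bot", u)
    r <- unit_fwd(m, nm, X, shape, training)
    if (want_cache) caches[[nm]] <- r$cache
    X <- r$out
  }
  for (i in rev(seq_len(cfg$depth))) {
    if (want_cache) caches[[paste0("upshape", i)]] <- shape
    X <- up_fwd(X, shape)
    shape <- c(shape[1] * 2L, shape[2] * 2L, N)
    r <- unit_fwd(m, paste0("up", i), X, shape, training)
    if (want_cache) caches[[paste0("up", i)]] <- r$cache
    X <- cbind(r$out, skips[[i]])
    for (u in c("a", "b")) {
      nm <- paste0("dec", i, u)
      r <- unit_fwd(m, nm, X, shape, training)
      if (want_cache) caches[[nm]] <- r$cache
      X <- r$out
    }
  }
  p <- m$params[["head"]]
  logits <- conv_fwd(X, p$W, p$b, shape)
  if (want_cache) caches[["head"]] <- list(X = X, shape = shape)
  list(prob = 1 / (1 + exp(-logits)), caches = caches)
}

# Backward pass from d(loss)/d(logits); returns gradient list mirroring params
unet_backward_mat <- function(m, caches, dlogits) {
  cfg <- m$cfg
  grads <- lapply(m$params, function(p) lapply(p, function(q) NULL))
  hc <- caches[["head"]]
  cb <- conv_bwd(dlogits, hc$X, m$params$head$W, hc$shape)
  grads$head$W <- cb$dW; grads$head$b <- cb$db
  dX <- cb$dX
  dskip <- list()
  for (i in seq_len(cfg$depth)) {
    for (u in c("b", "a")) {
      nm <- paste0("dec", i, u)
      r <- unit_bwd(m, nm, dX, caches[[nm]], grads)
      grads <- r$grads; dX <- r$dX
    }
    nch <- ncol(dX) %/% 2L
    dup <- dX[, seq_len(nch), drop = FALSE]
    dskip[[i]] <- dX[, nch + seq_len(nch), drop = FALSE]
    r <- unit_bwd(m, paste0("up", i), dup, caches[[paste0("up", i)]], grads)
    grads <- r$grads
    dX <- up_bwd(r$dX, caches[[paste0("upshape", i)]])
  }
  for (u in c("b", "a")) {
    nm <- paste0("bot", u)
    r <- unit_bwd(m, nm, dX, caches[[nm]], grads)
    grads <- r$grads; dX <- r$dX
  }
  for (i in rev(seq_len(cfg$depth))) {
    pc <- caches[[paste0("pool", i)]]
    dX <- pool_bwd(dX, pc$arg, pc$shape, pc$n_in, ncol(dX))
    dX <- dX + dskip[[i]]
    for (u in c("b", "a")) {
      nm <- paste0("enc", i, u)
      r <- unit_bwd(m, nm, dX, caches[[nm]], grads)
      grads <- r$grads; dX <- r$dX
    }
  }
  grads
}

# batch of slices (H, W, N) array -> (H*W*N) x 1 matrix
batch_to_mat <- function(batch) {
  d <- dim(batch)
  if (is.na(d[3])) d[3] <- 1L
  matrix(as.numeric(batch), ncol = 1L)
}

#' Forward pass: per-pixel membership for a stack of slices
#'
#' Evaluation-mode inference (batch normalization uses running statistics;
#' output is a pure function of the input).
#'
#' @param m A `unet_model` from [build_unet()] or [train_model()].
#' @param batch A 2D slice or 3D array `(rows, cols, n_slices)` matching the
#'   configured input shape.
#' @return Array of the same spatial shape with values strictly in `(0, 1)`.
#' @export
forward <- function(m, batch) {
  stopifnot(inherits(m, "unet_model"))
  if (length(dim(batch)) == 2L) dim(batch) <- c(dim(batch), 1L)
  d <- dim(batch)
  if (d[1] != m$cfg$in_shape[1] || d[2] != m$cfg$in_shape[2])
    stop(sprintf("slice shape %dx%d does not match model input %dx%d",
                 d[1], d[2], m$cfg$in_shape[1], m$cfg$in_shape[2]))
  r <- unet_forward_mat(m, batch_to_mat(batch), d[3], training = FALSE)
  array(r$prob, d)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture configuration, all parameters and
#' the batch-norm running statistics.
#'
#' @param m A `unet_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `unet_model` (load).
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "unet_model"))
  saveRDS(list(cfg = m$cfg, params = m$params, state = m$state), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  m <- new.env(parent = emptyenv())
  m$cfg <- obj$cfg; m$params <- obj$params; m$state <- obj$state
  m$n_parameters <- sum(vapply(obj$params, function(p)
    sum(vapply(p, length, integer(1))), numeric(1)))
  class(m) <- "unet_model"
  m
}
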