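#' Normalized mutual information between two equally shaped volumes
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` over a joint intensity histogram. Used as
#' the registration similarity because T1-w and FLAIR are different contrasts:
#' corresponding tissues need not have similar intensities, only a consistent
#' intensity relationship.
#'
#' @param a,b Numeric arrays/vectors of identical length.
#' @param nbins Histogram bins per image (default 32).
#' @return NMI value (>= 1; higher means better aligned).
#' @export
normalized_mutual_information <- function(a, b, nbins = 32) {
  ia <- hist_bins(as.numeric(a), nbins)
  ib <- hist_bins(as.numeric(b), nbins)
  nmi_from_bins(ia, ib, nbins)
}

hist_bins <- function(x, nbins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(1L, length(x)))
  pmin.int(as.integer(floor((x - lo) / (hi - lo) * nbins)) + 1L, nbins)
}

nmi_from_bins <- function(ia, ib, nbins) {
  joint <- tabulate(ia + nbins * (ib - 1L), nbins * nbins)
  p <- joint / sum(joint)
  pa <- rowSums(matrix(p, nbins, nbins))
  pb <- colSums(matrix(p, nbins, nbins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  h12 <- ent(p)
  if (h12 == 0) return(1)
  (ent(pa) + ent(pb)) / h12
}

# Precompute the in-plane sampling geometry of a volume once, then evaluate
# resampling under candidate transforms cheaply inside the optimizer loop.
transform_sampler <- function(v) {
  d <- dim(v$data)
  sx <- v$spacing[1]; sy <- v$spacing[2]
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  ij <- expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                    KEEP.OUT.ATTRS = FALSE)
  u <- rep((ij$i - cx) * sx, d[3])
  w <- rep((ij$j - cy) * sy, d[3])
  zi <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  vol <- as.numeric(v$data)
  function(par) {
    ct <- cos(par[3]); st <- sin(par[3])
    xi <- (ct * u - st * w + par[1]) / sx + cx
    yi <- (st * u + ct * w + par[2]) / sy + cy
    cpp_sample3(vol, as.integer(d), xi, yi, zi, 2L)
  }
}

downsample2_inplane <- function(v) {
  d <- dim(v$data)
  resize_inplane(v, pmax(8L, as.integer(d[1:2] / 2)), "spline")
}

#' In-plane rigid registration of FLAIR to T1-w
#'
#' Finds the single in-plane rigid transform (one per volume; slices are
#' paired by index) that maximizes normalized mutual information between the
#' transformed moving volume and the fixed volume. Optimization is a
#' multi-resolution derivative-free Nelder-Mead search starting from the
#' identity, run at a 2x in-plane downsampled level and refined at full
#' resolution.
#'
#' @param moving The volume to align (typically FLAIR).
#' @param fixed The reference volume (typically T1-w); must share grid shape
#'   and spacing with `moving` (call after reslicing).
#' @param nbins Histogram bins for the similarity (default 32).
#' @param max_iter Nelder-Mead iteration cap per level (default 300).
#' @return A list with `transform` (the [rigid2d()] that aligns `moving` to
#'   `fixed` when passed to [apply_transform()]), `aligned` (the resampled
#'   moving volume) and `nmi` (similarity at the optimum).
#' @export
register_rigid_inplane <- function(moving, fixed, nbins = 32, max_iter = 300) {
  stopifnot_volume(moving, "moving"); stopifnot_volume(fixed, "fixed")
  if (!identical(dim(moving$data), dim(fixed$data)) ||
      !isTRUE(all.equal(moving$spacing, fixed$spacing)))
    stop("moving and fixed must share grid shape and spacing")

  objective <- function(mov, fix) {
    sampler <- transform_sampler(mov)
    ifix <- hist_bins(as.numeric(fix$data), nbins)
    function(par) -nmi_from_bins(hist_bins(sampler(par), nbins), ifix, nbins)
  }

  # linear (high-kappa) diffusion acts as a small Gaussian blur; smoothing
  # both images regularizes the histogram-based similarity surface
  blur <- function(v, iters) anisotropic_diffuse(
    v, diffusion_config(iterations = iters, kappa = 1e8, dt = 0.25))

  par <- c(0, 0, 0)
  # coarse level: 2x in-plane downsampling + blur, multi-start search so a
  # single local optimum of the similarity cannot trap the registration
  if (all(dim(moving$data)[1:2] >= 32L)) {
    f_coarse <- objective(blur(downsample2_inplane(moving), 2),
                          blur(downsample2_inplane(fixed), 2))
    starts <- expand.grid(tx = c(-3, 0, 3), ty = c(-3, 0, 3),
                          th = c(-0.06, 0, 0.06))
    best <- Inf
    for (s in seq_len(nrow(starts))) {
      fit0 <- stats::optim(as.numeric(starts[s, ]), f_coarse,
                           method = "Nelder-Mead",
                           control = list(maxit = 80,
                                          parscale = c(1, 1, 0.02)))
      if (fit0$value < best) { best <- fit0$value; par <- fit0$par }
    }
    par <- stats::optim(par, f_coarse, method = "Nelder-Mead",
                        control = list(maxit = max_iter,
                                       parscale = c(1, 1, 0.02)))$par
  }
  f_fine <- objective(blur(moving, 2), blur(fixed, 2))
  fit <- stats::optim(par, f_fine, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-10,
                                     parscale = c(0.5, 0.5, 0.01)))
  # restart the simplex at the optimum with a tighter scale; Nelder-Mead can
  # stall with a collapsed simplex, a restart recovers the last digits
  fit <- stats::optim(fit$par, f_fine, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-12,
                                     parscale = c(0.1, 0.1, 0.002)))
  tr <- rigid2d(fit$par[1], fit$par[2], fit$par[3])
  list(transform = tr,
       aligned = apply_transform(moving, tr, "spline"),
       nmi = -fit$value)
}
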