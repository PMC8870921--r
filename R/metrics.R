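#' Voxel-wise confusion counts between two binary masks
#'
#' @param pred,truth Binary mask `volume`s (or plain 0/1 arrays) of identical
#'   shape.
#' @return A `confusion_counts` list with fields `tp`, `fp`, `fn`, `tn`
#'   summing to the total voxel count.
#' @export
confusion <- function(pred, truth) {
  p <- if (is_volume(pred)) pred$data else pred
  t <- if (is_volume(truth)) truth$data else truth
  if (!identical(dim(p), dim(t)) && length(p) != length(t))
    stop("pred and truth shapes differ")
  if (!is_binary_data(p) || !is_binary_data(t)) stop("masks must be binary")
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  tn <- sum(p == 0 & t == 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

# An undefined ratio (empty denominator) is vacuously perfect: comparing an
# empty prediction with an empty truth is agreement, not failure. Flagged via
# the "degenerate" attribute so callers can tell convention from measurement.
safe_ratio <- function(num, den) {
  if (den == 0) structure(1, degenerate = TRUE) else num / den
}

#' Segmentation performance measures from confusion counts
#'
#' Dice `2tp/(2tp+fp+fn)`, accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`,
#' sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)`. When a denominator
#' is zero (e.g. Dice of two empty masks) the value is 1 by convention and
#' carries a `degenerate` attribute, since lesion-free subjects are legal
#' inputs.
#'
#' @param c A `confusion_counts` object from [confusion()].
#' @return The metric in `[0, 1]`.
#' @name seg-metrics
NULL

#' @rdname seg-metrics
#' @export
dice <- function(c) safe_ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn)

#' @rdname seg-metrics
#' @export
accuracy <- function(c) safe_ratio(c$tp + c$tn, c$tp + c$fp + c$fn + c$tn)

#' @rdname seg-metrics
#' @export
precision <- function(c) safe_ratio(c$tp, c$tp + c$fp)

#' @rdname seg-metrics
#' @export
sensitivity <- function(c) safe_ratio(c$tp, c$tp + c$fn)

#' @rdname seg-metrics
#' @export
specificity <- function(c) safe_ratio(c$tn, c$tn + c$fp)

#' All five performance measures at once
#'
#' @param pred,truth Binary masks (volumes or 0/1 arrays) of identical shape.
#' @return Named numeric vector with `dice`, `accuracy`, `precision`,
#'   `sensitivity`, `specificity`.
#' @export
seg_metrics <- function(pred, truth) {
  cc <- confusion(pred, truth)
  c(dice = as.numeric(dice(cc)), accuracy = as.numeric(accuracy(cc)),
    precision = as.numeric(precision(cc)),
    sensitivity = as.numeric(sensitivity(cc)),
    specificity = as.numeric(specificity(cc)))
}

#' Bland-Altman agreement between automatic and manual volumes
#'
#' Computes the bias (mean of `auto - manual`), the 95% limits of agreement
#' `bias +/- 1.96 * SD(differences)` and the squared Pearson correlation of
#' the two volume series, plus the per-case means and differences for the
#' agreement plot.
#'
#' @param auto,manual Numeric vectors of per-case volumes (mm^3), equal
#'   length >= 2.
#' @return An `agreement_stats` list: `bias`, `loa_low`, `loa_high`,
#'   `r_squared`, `n`, and a data frame `plot_data` with columns `mean` and
#'   `difference`.
#' @export
bland_altman <- function(auto, manual) {
  auto <- as.numeric(auto); manual <- as.numeric(manual)
  if (length(auto) != length(manual)) stop("series lengths differ")
  if (length(auto) < 2) stop("need at least 2 cases")
  diffs <- auto - manual
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  r2 <- if (stats::sd(auto) == 0 || stats::sd(manual) == 0) {
    structure(1, degenerate = TRUE)
  } else {
    stats::cor(auto, manual)^2
  }
  structure(list(bias = bias,
                 loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s,
                 r_squared = r2,
                 n = length(auto),
                 plot_data = data.frame(mean = (auto + manual) / 2,
                                        difference = diffs)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement over %d cases: bias %.2f mm^3, LoA [%.2f, %.2f], R^2 = %.4f>\n",
              x$n, x$bias, x$loa_low, x$loa_high, as.numeric(x$r_squared)))
  invisible(x)
}
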