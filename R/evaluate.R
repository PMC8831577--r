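as_binary_grid <- function(x) {
  v <- if (inherits(x, "mask_volume")) x$voxels else x
  if (!all(v %in% c(0, 1, FALSE, TRUE))) stop("grid must be binary")
  v != 0
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)` for two binary grids of the same shape.
#' When both grids are empty the score is 1 (two empty segmentations
#' agree perfectly); summaries can exclude such slices explicitly.
#'
#' @param a,b binary arrays/matrices or [mask_volume()]s of equal shape.
#' @return Score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_binary_grid(a); b <- as_binary_grid(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Intersection over union (Jaccard index)
#'
#' `|A n B| / (|A| + |B| - |A n B|)`; both-empty convention 1, matching
#' [dice()]. Related to Dice by `iou = dice / (2 - dice)`.
#'
#' @inheritParams dice
#' @return Score in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as_binary_grid(a); b <- as_binary_grid(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  inter <- sum(a & b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Volume and per-slice Dice report
#'
#' Volume Dice over all in-extent voxels plus a Dice value per in-extent
#' axial slice, with slice-mean and sd summaries.
#'
#' @param pred,truth aligned [mask_volume()]s (or binary arrays).
#' @param extent optional [heart_extent()]; when omitted all slices count.
#' @return `list(volume_dice, per_slice_dice, slice_mean, slice_sd)`.
#' @export
dice_report <- function(pred, truth, extent = NULL) {
  p <- as_binary_grid(pred); t <- as_binary_grid(truth)
  if (!identical(dim(p), dim(t))) stop("shape mismatch")
  idx <- if (is.null(extent)) seq_len(dim(p)[3]) else {
    if (extent$top > dim(p)[3]) stop("extent exceeds mask")
    extent$bottom:extent$top
  }
  p <- p[, , idx, drop = FALSE]; t <- t[, , idx, drop = FALSE]
  per_slice <- vapply(seq_along(idx), function(i) {
    dice(p[, , i], t[, , i])
  }, 0)
  list(volume_dice = dice(p, t),
       per_slice_dice = per_slice,
       slice_mean = mean(per_slice),
       slice_sd = stats::sd(per_slice))
}

#' Quartile slice groups
#'
#' Partitions the heart slice sequence into four contiguous
#' bottom-to-top groups of as-equal-as-possible size; when `n mod 4 = r`,
#' the first `r` groups take the extra slice. Used to localise where in
#' the heart segmentation errors concentrate.
#'
#' @param n_slices number of heart slices (>= 4).
#' @return List of four integer index vectors (1-based, contiguous).
#' @export
quartile_groups <- function(n_slices) {
  n <- as.integer(n_slices)
  if (is.na(n) || n < 4L) stop("quartile grouping needs at least 4 slices")
  sizes <- rep(n %/% 4L, 4L)
  r <- n %% 4L
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-4L] + 1L)
  lapply(1:4, function(i) seq.int(starts[i], ends[i]))
}

#' Bland-Altman agreement summary
#'
#' Paired differences `d_i = test_i - reference_i` (automated minus
#' manual by default orientation); bias is their mean, sd uses the n-1
#' denominator, and the limits of agreement are `bias +/- 1.96 * sd`.
#'
#' @param reference,test equal-length numeric vectors (n >= 2).
#' @return An object of class `agreement_stats` with fields `bias`, `sd`,
#'   `loa_low`, `loa_high`, `n` and the differences `d`.
#' @export
bland_altman <- function(reference, test) {
  if (length(reference) != length(test)) stop("length mismatch")
  if (length(reference) < 2L) stop("need at least 2 pairs")
  d <- test - reference
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d), d = d),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement> bias %.3f, sd %.3f, LOA [%.3f, %.3f], n = %d\n",
              x$bias, x$sd, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Origin-constrained regression with correlation
#'
#' Fits `y = m x` through the origin (`m = sum(x*y) / sum(x^2)`) and
#' reports the ordinary Pearson correlation of `(x, y)` with its
#' two-sided p-value (t transform, n - 2 df).
#'
#' @param x,y equal-length numeric vectors, `length >= 2`, `x` not all 0.
#' @return An object of class `origin_fit` with fields `slope`, `r`, `p`.
#' @export
origin_fit <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 points")
  if (all(x == 0)) stop("degenerate x: all zero")
  slope <- sum(x * y) / sum(x^2)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    r <- stats::cor(x, y)
    p <- if (n <= 2) NA_real_ else if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(slope = slope, r = r, p = p, n = n),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("<origin_fit> slope %.4f, R %.4f, p %.3g, n = %d\n",
              x$slope, x$r, x$p, x$n))
  invisible(x)
}

#' Percent volume error
#'
#' `100 * (auto - manual) / manual`; a cohort of pairs is summarised as
#' mean and sd of the per-scan percent errors.
#'
#' @param auto,manual volumes in cm^3 (vectors allowed); `manual > 0`.
#' @return For scalars, the percent error; for vectors, a list with
#'   `percent` (per pair), `mean`, `sd`.
#' @export
percent_error <- function(auto, manual) {
  if (any(manual <= 0)) stop("manual volume must be positive")
  pe <- 100 * (auto - manual) / manual
  if (length(pe) == 1L) return(pe)
  list(percent = pe, mean = mean(pe), sd = stats::sd(pe))
}

#' Paired t-test on matched measurements
#'
#' Standard two-sided paired t on the differences; zero difference
#' variance (with a non-zero mean impossible to scale) is flagged as an
#' error rather than reported as an infinite statistic.
#'
#' @param x,y equal-length numeric vectors (n >= 2).
#' @return `list(t, p, df, mean_diff)`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1L,
                                 mean_diff = 0))
    stop("degenerate paired t: zero difference variance")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}
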