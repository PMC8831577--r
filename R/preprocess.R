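#' HU attention window
#'
#' A display-style linear window on the Hounsfield scale, given as
#' width/level. The default 350/40 keeps the faint pericardium contrast
#' alive when the volume is quantised to 8 bits for the network.
#'
#' @param width window width in HU (> 0).
#' @param level window centre in HU.
#' @return An object of class `window_spec` with derived `lo = level -
#'   width/2` and `hi = level + width/2`.
#' @export
window_spec <- function(width = 350, level = 40) {
  width <- as.numeric(width); level <- as.numeric(level)
  if (!is.finite(width) || width <= 0) stop("window width must be positive")
  structure(list(width = width, level = level,
                 lo = level - width / 2, hi = level + width / 2),
            class = "window_spec")
}

round_half_up <- function(x) floor(x + 0.5)

#' Map a HU volume to 8-bit through an attention window
#'
#' Linear clamp-and-rescale: `v8 = round(255 * clamp((HU - lo)/(hi - lo),
#' 0, 1))` with round-half-up. The mapping is monotone non-decreasing in
#' HU; everything at or below `lo` maps to 0 and at or above `hi` to 255.
#'
#' @param volume a [ct_volume()] or plain numeric array of HU.
#' @param spec a [window_spec()].
#' @return Integer array of the same shape with values in 0..255.
#' @export
hu_window_to_8bit <- function(volume, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  hu <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  frac <- pmin(pmax((hu - spec$lo) / (spec$hi - spec$lo), 0), 1)
  out <- round_half_up(255 * frac)
  storage.mode(out) <- "integer"
  out
}

#' Bisected look-ahead slab plan
#'
#' Splits the heart slices into two halves and sequences each toward the
#' middle: the lower half bottom-to-middle with look-ahead step `s = +1`,
#' the upper half top-to-middle with `s = -1`. Along each presented
#' half-sequence the pericardial sac cross-section is non-decreasing, so
#' the network always sees the sac growing. For odd slice counts the lower
#' half takes `floor(n/2)` slices and the upper half the remainder.
#'
#' @param extent a [heart_extent()] (or a plain slice count `n >= 3`).
#' @return A `slab_plan`: data.frame with columns `k` (1-based target
#'   slice within the extent) and `s` (step), plus attribute `split`
#'   (number of lower-half entries). Every heart slice appears exactly
#'   once as a target.
#' @export
bisect_plan <- function(extent) {
  n <- if (inherits(extent, "heart_extent")) extent_n_slices(extent)
       else as.integer(extent)
  if (n < 3L) stop("bisect plan needs at least 3 heart slices")
  split <- n %/% 2L
  lower <- data.frame(k = seq_len(split), s = 1L)
  upper <- data.frame(k = seq.int(n, split + 1L), s = -1L)
  plan <- rbind(lower, upper)
  attr(plan, "split") <- split
  attr(plan, "n") <- n
  class(plan) <- c("slab_plan", "data.frame")
  plan
}

#' Sequential (non-bisected) slab plan
#'
#' Ablation counterpart of [bisect_plan()]: all slices bottom-to-top with
#' step `+1`, so the top-most targets look ahead past the extent border
#' (where slab assembly clamps by replication).
#'
#' @inheritParams bisect_plan
#' @return A `slab_plan` with `split = n`.
#' @export
sequential_plan <- function(extent) {
  n <- if (inherits(extent, "heart_extent")) extent_n_slices(extent)
       else as.integer(extent)
  if (n < 3L) stop("slab plan needs at least 3 heart slices")
  plan <- data.frame(k = seq_len(n), s = 1L)
  attr(plan, "split") <- n
  attr(plan, "n") <- n
  class(plan) <- c("slab_plan", "data.frame")
  plan
}

#' Assemble a three-slice look-ahead slab
#'
#' Stacks slices `(k, k+s, k+2s)` of the windowed heart volume into the
#' three channels of a slab; `k` is the slice of interest and the other
#' two are the upcoming slices on the side of increasing sac area.
#' Look-ahead indices may cross the mid-heart line; indices outside the
#' extent (possible only near the extent borders) are clamped by
#' replicating the nearest in-extent slice.
#'
#' @param volume8 8-bit heart volume (array `[row, col, slice]`, already
#'   cropped to the heart extent and windowed).
#' @param k 1-based target slice index within the extent.
#' @param s look-ahead step, `+1` or `-1`.
#' @return A `slab`: integer array `[row, col, 3]` with attributes
#'   `target` (= k) and `step` (= s).
#' @export
assemble_slab <- function(volume8, k, s) {
  n <- dim(volume8)[3]
  k <- as.integer(k); s <- as.integer(s)
  if (!s %in% c(-1L, 1L)) stop("step must be +1 or -1")
  if (k < 1L || k > n) stop("target slice outside extent")
  idx <- pmin(pmax(c(k, k + s, k + 2L * s), 1L), n)
  slab <- volume8[, , idx, drop = FALSE]
  storage.mode(slab) <- "integer"
  structure(slab, target = k, step = s, class = "slab")
}

#' Median filter with a physical (mm) kernel
#'
#' Rank-median over an axis-aligned box whose per-axis extent is derived
#' from the requested physical kernel: `n_ax = 2 * floor(kernel_mm /
#' (2 * spacing_ax)) + 1` voxels, i.e. the largest odd voxel count whose
#' physical span does not exceed `kernel_mm`. With 2.5 mm slices and a
#' 3 mm kernel this degenerates to an in-plane median (z count 1), which
#' is reported via a message. Edges use nearest-value (replicate) padding.
#'
#' @param volume a [ct_volume()].
#' @param kernel_mm physical kernel edge length in mm (default 3).
#' @param quiet suppress the kernel-size message.
#' @return A filtered [ct_volume()].
#' @export
median_filter_mm <- function(volume, kernel_mm = 3, quiet = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.finite(kernel_mm) || kernel_mm <= 0) stop("kernel_mm must be > 0")
  nax <- 2L * as.integer(kernel_mm / (2 * volume$spacing)) + 1L
  if (!quiet) {
    message(sprintf("median filter %g mm -> voxel kernel (%d, %d, %d)%s",
                    kernel_mm, nax[1], nax[2], nax[3],
                    if (nax[3] == 1L) " [in-plane only at this slice spacing]"
                    else ""))
  }
  if (all(nax == 1L)) return(volume)
  filtered <- cpp_median3d(volume$voxels, nax[1], nax[2], nax[3])
  ct_volume(filtered, spacing = volume$spacing, scan_id = volume$scan_id)
}
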