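#' Fat attenuation window
#'
#' The standard CT fat range. Both bounds are inclusive: a voxel at
#' exactly -190 or -30 HU counts as fat.
#'
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return An object of class `fat_window`.
#' @export
fat_window <- function(lo = -190, hi = -30) {
  if (!(lo < hi)) stop("fat window requires lo < hi")
  structure(list(lo = lo, hi = hi), class = "fat_window")
}

#' Threshold fat within the pericardial sac
#'
#' A voxel is epicardial adipose tissue iff it lies inside the
#' sac-interior mask and its HU value falls in the closed fat window.
#' The volume passed here should already be noise-reduced (see
#' [median_filter_mm()] and [quantify_eat()]).
#'
#' @param volume a [ct_volume()].
#' @param sac_mask a [mask_volume()] aligned to `volume`.
#' @param window a [fat_window()].
#' @return A [mask_volume()] with label `"eat"`.
#' @export
threshold_fat <- function(volume, sac_mask, window = fat_window()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(sac_mask, "mask_volume"),
            inherits(window, "fat_window"))
  check_aligned(volume, sac_mask)
  eat <- (sac_mask$voxels == 1L) &
    (volume$voxels >= window$lo) & (volume$voxels <= window$hi)
  mask_volume(array(as.integer(eat), dim = dim(volume$voxels)),
              spacing = volume$spacing, label = "eat")
}

#' Mask volume in cubic centimetres
#'
#' `count(mask == 1) * dx * dy * dz / 1000`.
#'
#' @param mask a [mask_volume()].
#' @return Volume in cm^3.
#' @export
eat_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Mean HU over a mask
#'
#' @param volume a [ct_volume()].
#' @param mask a non-empty [mask_volume()] aligned to `volume`.
#' @return Mean HU of the masked voxels.
#' @export
eat_mean_hu <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "mask_volume"))
  check_aligned(volume, mask)
  if (sum(mask$voxels) == 0L) stop("mean HU undefined for an empty mask")
  mean(volume$voxels[mask$voxels == 1L])
}

#' Per-axial-slice mask volume
#'
#' @param mask a [mask_volume()].
#' @return Numeric vector, one cm^3 value per axial slice; sums to
#'   [eat_volume_cm3()].
#' @export
per_slice_volume <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  counts <- apply(mask$voxels, 3, sum)
  counts * prod(mask$spacing) / 1000
}

#' Quantify epicardial adipose tissue
#'
#' The full quantification step: median-filter the HU volume (physical
#' 3 mm kernel by default, mirroring the manual protocol), threshold the
#' fat window inside the sac, and report the EAT mask, total volume,
#' mean HU (on the filtered volume, for consistency with the mask) and
#' per-slice volumes.
#'
#' @param volume a [ct_volume()].
#' @param sac_mask pericardial-interior [mask_volume()].
#' @param window a [fat_window()].
#' @param median_kernel_mm kernel for noise reduction before
#'   thresholding; `NULL` or 0 skips filtering.
#' @return An object of class `eat_result`: fields `eat_mask`,
#'   `total_volume` (cm^3), `mean_hu` (NA when no fat voxel survives)
#'   and `per_slice_volume`.
#' @export
quantify_eat <- function(volume, sac_mask, window = fat_window(),
                         median_kernel_mm = 3) {
  filtered <- if (is.null(median_kernel_mm) || median_kernel_mm <= 0) volume
              else median_filter_mm(volume, median_kernel_mm, quiet = TRUE)
  eat <- threshold_fat(filtered, sac_mask, window)
  structure(
    list(
      eat_mask = eat,
      total_volume = eat_volume_cm3(eat),
      mean_hu = if (sum(eat$voxels) > 0L) eat_mean_hu(filtered, eat)
                else NA_real_,
      per_slice_volume = per_slice_volume(eat)
    ),
    class = "eat_result"
  )
}

#' @export
print.eat_result <- function(x, ...) {
  cat(sprintf("<eat_result> EAT volume %.2f cm^3, mean HU %s, %d slices\n",
              x$total_volume,
              if (is.na(x$mean_hu)) "NA" else sprintf("%.1f", x$mean_hu),
              length(x$per_slice_volume)))
  invisible(x)
}
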