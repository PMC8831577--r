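#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield units together with its
#' physical voxel spacing and a fixed anatomical slice convention:
#' slice 1 is the most inferior axial slice and the slice index increases
#' superiorly. Voxels are indexed `[row, column, slice]` and stored as
#' floating point HU; nothing is ever window-compressed in memory.
#'
#' @param voxels 3D numeric array of HU values, `[row, column, slice]`.
#' @param spacing numeric length-3: (row mm, column mm, slice mm), all > 0.
#' @param scan_id opaque scan identifier string.
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `slice_order` (always `"inferior_to_superior"`) and `scan_id`.
#' @export
ct_volume <- function(voxels, spacing, scan_id = "scan") {
  voxels <- as_volume_array(voxels)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive finite values (row, column, slice mm)")
  }
  if (dim(voxels)[3] < 1L) stop("volume must contain at least one slice")
  if (any(!is.finite(voxels))) stop("HU values must be finite")
  structure(
    list(
      voxels = voxels,
      spacing = spacing,
      slice_order = "inferior_to_superior",
      scan_id = as.character(scan_id)[1]
    ),
    class = "ct_volume"
  )
}

as_volume_array <- function(voxels) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("voxels must be a 3D array [row, column, slice]")
  }
  storage.mode(voxels) <- "double"
  voxels
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume '%s'> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU [%.0f, %.0f]\n",
    x$scan_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Heart extent along the slice axis
#'
#' The manually supplied first (most inferior) and last (most superior)
#' axial slices containing the heart, as 1-based inclusive indices into a
#' [ct_volume()]. A valid extent spans at least 3 slices so that a
#' three-slice slab can always be assembled.
#'
#' @param bottom,top 1-based inclusive slice indices, `bottom <= top`.
#' @return An object of class `heart_extent`.
#' @export
heart_extent <- function(bottom, top) {
  bottom <- as.integer(bottom); top <- as.integer(top)
  if (is.na(bottom) || is.na(top) || bottom < 1L || top < bottom) {
    stop("invalid heart extent: need 1 <= bottom <= top")
  }
  if (top - bottom + 1L < 3L) {
    stop("heart extent must span at least 3 slices")
  }
  structure(list(bottom = bottom, top = top), class = "heart_extent")
}

extent_n_slices <- function(extent) extent$top - extent$bottom + 1L

validate_extent <- function(extent, volume) {
  stopifnot(inherits(extent, "heart_extent"), inherits(volume, "ct_volume"))
  if (extent$top > dim(volume$voxels)[3]) {
    stop("heart extent exceeds the number of slices in the volume")
  }
  invisible(extent)
}

#' Binary mask volume aligned to a CT volume
#'
#' @param voxels 3D array with values in \{0, 1\}.
#' @param spacing voxel spacing in mm, normally inherited from the parent
#'   [ct_volume()].
#' @param label role of the mask: `"sac_interior"` (pericardial interior)
#'   or `"eat"` (epicardial adipose tissue).
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(voxels, spacing, label = c("sac_interior", "eat")) {
  label <- match.arg(label)
  voxels <- as_volume_array(voxels)
  if (!all(voxels %in% c(0, 1))) stop("mask values must be 0 or 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid mask spacing")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = spacing, label = label),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mask_volume '%s'> %d x %d x %d, %d foreground voxels\n",
              x$label, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    stop("volume/mask shapes do not match")
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6) {
    stop("volume/mask spacings do not match")
  }
  invisible(TRUE)
}

#' Load an axial CT series from a DICOM directory
#'
#' Reads every `.dcm` file in `directory`, checks that they form a single
#' axial series, converts stored values to HU with the per-file rescale
#' (`HU = stored * slope + intercept`), and stacks slices in ascending
#' anatomical z so slice 1 is the most inferior. The result is independent
#' of the order in which files are listed on disk.
#'
#' @param directory path containing exactly one CT series.
#' @return A [ct_volume()].
#' @details Inter-slice spacing must be uniform to within 1% of its median;
#'   mixed series UIDs, missing position or rescale tags, and inconsistent
#'   in-plane geometry are errors.
#' @export
load_ct_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files found in ", directory)
  slices <- lapply(files, read_dicom_file)

  uid <- unique(vapply(slices, function(s) s$series_uid, ""))
  if (length(uid) != 1L) stop("mixed series identifiers in ", directory)

  z <- vapply(slices, function(s) {
    if (is.null(s$position)) stop("missing ImagePositionPatient tag")
    s$position[3]
  }, 0)
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]

  n <- length(slices)
  if (n > 1L) {
    dz <- diff(z)
    if (any(dz <= 0)) stop("duplicate or non-increasing slice positions")
    if (n > 2L && (max(dz) - min(dz)) > 0.01 * stats::median(dz)) {
      stop("non-uniform inter-slice spacing beyond 1% tolerance")
    }
    slice_mm <- stats::median(dz)
  } else {
    slice_mm <- slices[[1]]$slice_thickness
    if (is.null(slice_mm)) stop("cannot determine slice spacing")
  }

  shp <- dim(slices[[1]]$pixels)
  ps <- slices[[1]]$pixel_spacing
  if (is.null(ps)) stop("missing PixelSpacing tag")
  hu <- array(0, dim = c(shp, n))
  for (i in seq_len(n)) {
    s <- slices[[i]]
    if (!identical(dim(s$pixels), shp)) stop("inconsistent slice dimensions")
    if (is.null(s$slope) || is.null(s$intercept)) {
      stop("missing rescale slope/intercept tags")
    }
    hu[, , i] <- s$pixels * s$slope + s$intercept
  }
  ct_volume(hu, spacing = c(ps[1], ps[2], slice_mm), scan_id = uid)
}

#' Write a CT volume as a DICOM series
#'
#' One file per axial slice, int16 stored values with rescale
#' slope 1 / intercept -1024 (so integer HU round-trip exactly), explicit
#' VR little endian. Primarily used to materialise synthetic phantoms in
#' the same format clinical scans arrive in.
#'
#' @param volume a [ct_volume()] whose HU values are integral.
#' @param directory output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_ct_series <- function(volume, directory) {
  stopifnot(inherits(volume, "ct_volume"))
  if (max(abs(volume$voxels - round(volume$voxels))) > 1e-9) {
    stop("write_ct_series requires integral HU values")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- dim(volume$voxels)[3]
  uid <- paste0("1.2.826.0.1.3680043.9999.", dicom_uid_suffix(volume$scan_id))
  paths <- character(n)
  for (i in seq_len(n)) {
    stored <- round(volume$voxels[, , i]) + 1024
    if (any(stored < -32768 | stored > 32767)) stop("HU out of int16 stored range")
    paths[i] <- file.path(directory, sprintf("slice_%04d.dcm", i))
    write_dicom_file(
      paths[i],
      pixels = stored,
      pixel_spacing = volume$spacing[1:2],
      slice_thickness = volume$spacing[3],
      position = c(0, 0, (i - 1) * volume$spacing[3]),
      instance = i,
      series_uid = uid,
      slope = 1, intercept = -1024
    )
  }
  invisible(paths)
}

dicom_uid_suffix <- function(id) {
  # deterministic numeric suffix from the scan id (UIDs must be digits/dots)
  s <- utf8ToInt(id)
  paste0(sum(s * seq_along(s)) %% 100000L, ".", length(s))
}

#' Save / load a binary mask as NIfTI
#'
#' Masks are written as unsigned 8-bit NIfTI with voxel spacing carried in
#' the header, values strictly in \{0, 1\}; the round trip is lossless.
#' On load the mask is checked against the parent CT volume's shape and a
#' file containing values other than 0/1 is rejected.
#'
#' @param mask a [mask_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `save_mask` invisibly returns `path`; `load_mask` returns a
#'   [mask_volume()].
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname save_mask
#' @param parent the [ct_volume()] the mask annotates.
#' @param label role tag to attach to the loaded mask.
#' @export
load_mask <- function(path, parent, label = c("sac_interior", "eat")) {
  label <- match.arg(label)
  stopifnot(inherits(parent, "ct_volume"))
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  if (!all(vox %in% c(0, 1))) stop("mask file contains non-binary values")
  if (!identical(dim(vox), dim(parent$voxels))) {
    stop("mask shape does not match parent volume")
  }
  mask_volume(vox, spacing = parent$spacing, label = label)
}

#' Crop a CT volume to a heart extent
#'
#' Keeps only the axial slices between `bottom` and `top` (inclusive);
#' the in-plane grid and spacing are unchanged and slice 1 of the result
#' is slice `bottom` of the input.
#'
#' @param volume a [ct_volume()].
#' @param extent a [heart_extent()] valid for `volume`.
#' @return A [ct_volume()] with `top - bottom + 1` slices.
#' @export
crop_to_extent <- function(volume, extent) {
  validate_extent(extent, volume)
  ct_volume(volume$voxels[, , extent$bottom:extent$top, drop = FALSE],
            spacing = volume$spacing, scan_id = volume$scan_id)
}

crop_mask_to_extent <- function(mask, extent) {
  stopifnot(inherits(mask, "mask_volume"))
  if (extent$top > dim(mask$voxels)[3]) stop("extent exceeds mask")
  mask_volume(mask$voxels[, , extent$bottom:extent$top, drop = FALSE],
              spacing = mask$spacing, label = mask$label)
}
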