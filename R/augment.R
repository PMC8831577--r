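#' Training augmentation configuration
#'
#' Enrichment used when fitting the per-slice segmenter: every training
#' slab is duplicated once with a random Gaussian blur (sigma drawn
#' uniformly below 2 pixels; the mask is never blurred), and each epoch
#' every item receives a fresh random rotation (-5..+5 degrees) and
#' isotropic scaling (0.9..1.1) applied identically to all three channels
#' and the mask about the image centre.
#'
#' @param rotation_deg length-2 rotation interval in degrees.
#' @param scale length-2 scale-factor interval.
#' @param blur_sigma_max strict upper bound for the blur sigma (pixels).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_deg = c(-5, 5), scale = c(0.9, 1.1),
                           blur_sigma_max = 2) {
  stopifnot(length(rotation_deg) == 2L, rotation_deg[1] <= rotation_deg[2],
            length(scale) == 2L, 0 < scale[1], scale[1] <= scale[2],
            blur_sigma_max > 0)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 scale = as.numeric(scale),
                 blur_sigma_max = as.numeric(blur_sigma_max)),
            class = "augment_config")
}

blur_slab <- function(image, sigma) {
  if (sigma < 1e-3) return(image)
  out <- image
  for (ch in seq_len(dim(image)[3])) {
    out[, , ch] <- EBImage::gblur(image[, , ch], sigma = sigma)
  }
  out
}

#' Duplicate training items with random blur
#'
#' Doubles the training set: each `(slab, mask)` item is followed by a
#' copy whose image channels are Gaussian-blurred with `sigma ~
#' Uniform(0, blur_sigma_max)`; the copy keeps the original mask
#' unchanged. Blur copies are created once, before epoch-wise geometric
#' augmentation.
#'
#' @param items non-empty list of `list(image = [row, col, 3] array,
#'   mask = binary matrix)`.
#' @param config an [augment_config()].
#' @return A list of `2 * length(items)` items, originals at odd
#'   positions, blurred copies at even positions.
#' @export
blur_duplicate <- function(items, config = augment_config()) {
  if (length(items) == 0L) stop("blur_duplicate requires a non-empty list")
  out <- vector("list", 2L * length(items))
  for (i in seq_along(items)) {
    item <- items[[i]]
    sigma <- stats::runif(1, 0, config$blur_sigma_max)
    out[[2L * i - 1L]] <- item
    out[[2L * i]] <- list(image = blur_slab(item$image, sigma),
                          mask = item$mask)
  }
  out
}

affine_matrix <- function(angle_deg, scale, center) {
  # maps input pixel p to scale * R(angle) (p - c) + c (EBImage convention:
  # first two rows are the linear map on (row, col), third row translation)
  th <- angle_deg * pi / 180
  a <- scale * cos(th); b <- scale * sin(th)
  lin <- rbind(c(a, b), c(-b, a))
  rbind(lin, center - as.vector(center %*% lin))
}

warp_rotate_scale <- function(x, angle_deg, scale, nearest = FALSE) {
  d <- dim(x)
  center <- matrix((d[1:2] + 1) / 2, nrow = 1)
  m <- affine_matrix(angle_deg, scale, center)
  y <- EBImage::affine(x, m, filter = if (nearest) "none" else "bilinear",
                       output.dim = d[1:2], bg.col = 0)
  array(as.numeric(y), dim = d)
}

#' Random rotation/scale of a slab and its mask
#'
#' Draws one rotation angle and one scale factor and applies the same
#' centre-anchored warp to all three slab channels (bilinear) and to the
#' mask (nearest neighbour, so it stays strictly binary). Pixels pulled in
#' from outside the frame are filled with 0, the 8-bit value of
#' below-window HU.
#'
#' @param image `[row, col, 3]` slab array (8-bit values).
#' @param mask binary matrix matching the slab in-plane shape.
#' @param config an [augment_config()].
#' @return `list(image, mask, angle, scale)`.
#' @export
random_geometric <- function(image, mask, config = augment_config()) {
  stopifnot(identical(dim(image)[1:2], dim(mask)))
  angle <- stats::runif(1, config$rotation_deg[1], config$rotation_deg[2])
  scale <- stats::runif(1, config$scale[1], config$scale[2])
  img <- warp_rotate_scale(image, angle, scale, nearest = FALSE)
  msk <- warp_rotate_scale(array(mask, dim = c(dim(mask), 1L)),
                           angle, scale, nearest = TRUE)[, , 1]
  storage.mode(msk) <- "integer"
  list(image = img, mask = msk, angle = angle, scale = scale)
}

#' Training presentation accounting
#'
#' Number of items after blur duplication and the total number of image
#' presentations over all epochs (each epoch re-presents every duplicated
#' item once, with fresh geometric augmentation).
#'
#' @param n_slices number of labelled training slices (>= 1).
#' @param epochs number of training epochs (>= 1).
#' @return `list(after_dup = 2 * n_slices, total = after_dup * epochs)`.
#' @export
presentation_count <- function(n_slices, epochs) {
  n_slices <- as.numeric(n_slices); epochs <- as.numeric(epochs)
  if (is.na(n_slices) || n_slices < 1 || n_slices != floor(n_slices)) {
    stop("n_slices must be a positive integer")
  }
  if (is.na(epochs) || epochs < 1 || epochs != floor(epochs)) {
    stop("epochs must be a positive integer")
  }
  after_dup <- 2 * n_slices
  list(after_dup = after_dup, total = after_dup * epochs)
}
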