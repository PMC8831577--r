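#' Synthetic cardiac phantom specification
#'
#' Describes a stack of axial slices emulating a non-contrast calcium
#' score scan: an elliptical body of soft tissue with lateral lung
#' fields, and a heart whose pericardial-sac interior cross-section
#' follows a unimodal radius profile `r(z) = r_max * sqrt(1 - ((z -
#' z_mid) / h)^2)` - rising from the heart bottom to the middle and
#' falling towards the top. Inside the sac, epicardial fat sits as an
#' annulus against the thin pericardial wall and the remaining interior
#' is blood/soft tissue; a paracardial fat ring lies outside the wall.
#' Per-voxel HU values are drawn per compartment, rounded to integer HU
#' (as scanners store them), and optional Gaussian noise is added.
#'
#' EAT voxels draw uniformly from `[-180, -40]` HU - strictly inside the
#' standard fat window with a 10 HU guard band on each side - so at noise
#' zero every EAT voxel classifies as fat and every other in-sac voxel
#' does not. With `median_stable_mm > 0` the noise-free compartments are
#' additionally made a fixed point of the physical median filter of that
#' kernel, so fat-window recovery is exact even after noise reduction.
#'
#' @param shape in-plane grid (rows, cols); default 64 x 64 for tests,
#'   512 x 512 also works.
#' @param spacing voxel spacing (row, col, slice) in mm.
#' @param n_heart number of heart slices (>= 3).
#' @param pad padding slices below and above the heart (lung/soft tissue
#'   only), so heart-extent selection is meaningful.
#' @param r_max_mm maximal sac-interior radius in mm (mid-heart).
#' @param wall_mm pericardial wall thickness in mm (>= 1 in-plane voxel).
#' @param paracardial_mm thickness of the paracardial fat ring.
#' @param eat_fraction target EAT share of the sac-interior cross-section
#'   (realised as an inner annulus; a minimum annulus thickness of 3
#'   in-plane voxels keeps the geometry median-stable).
#' @param eat_mode `"annulus"` (default) or `"blobs"` (random fat
#'   deposits, for robustness tests; blob geometry is not median-stable).
#' @param hu named list of compartment HU levels.
#' @param noise_sd additive Gaussian noise sd in HU (default 0).
#' @param median_stable_mm median kernel (mm) the noise-free phantom is
#'   stabilised against; 0 disables.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L), spacing = c(0.7, 0.7, 2.5),
                         n_heart = 24L, pad = 4L, r_max_mm = 14,
                         wall_mm = 1.4, paracardial_mm = 2.1,
                         eat_fraction = 0.25,
                         eat_mode = c("annulus", "blobs"),
                         hu = list(blood = 40, wall = 20, paracardial = -90,
                                   body = 30, lung = -800, air = -1000),
                         noise_sd = 0, median_stable_mm = 3) {
  eat_mode <- match.arg(eat_mode)
  shape <- as.integer(shape); n_heart <- as.integer(n_heart)
  stopifnot(length(shape) == 2L, all(shape >= 16L), n_heart >= 3L,
            pad >= 0L, r_max_mm > 0, eat_fraction > 0, eat_fraction < 1,
            noise_sd >= 0)
  if (wall_mm < max(spacing[1:2])) {
    stop("pericardial wall must be at least one in-plane voxel thick")
  }
  fov <- shape * spacing[1:2]
  if (r_max_mm + wall_mm + paracardial_mm > min(fov) / 2 - 2 * max(spacing[1:2])) {
    stop("heart does not fit inside the frame")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 n_heart = n_heart, pad = as.integer(pad),
                 r_max_mm = r_max_mm, wall_mm = wall_mm,
                 paracardial_mm = paracardial_mm,
                 eat_fraction = eat_fraction, eat_mode = eat_mode,
                 hu = hu, noise_sd = noise_sd,
                 median_stable_mm = median_stable_mm),
            class = "phantom_spec")
}

phantom_radius_profile <- function(spec) {
  n <- spec$n_heart
  z_mid <- (n + 1) / 2
  h <- (n + 1) / 2
  spec$r_max_mm * sqrt(pmax(1 - ((seq_len(n) - z_mid) / h)^2, 0))
}

draw_eat_hu <- function(n) round(stats::runif(n, -180, -40))

#' Generate a synthetic cardiac CT phantom
#'
#' Builds the HU volume described by a [phantom_spec()] together with its
#' analytic ground truth: the pericardial-interior mask, the EAT mask,
#' the heart extent and the exact truth volumes (voxel count times voxel
#' volume). Reproducible for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return A `phantom`: `list(volume, sac, eat, extent, truth, spec,
#'   seed)` where `truth` holds `eat_cm3` and `sac_cm3`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(as.integer(seed))

  nr <- spec$shape[1]; nc <- spec$shape[2]
  nz <- spec$n_heart + 2L * spec$pad
  sp <- spec$spacing
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2

  rr <- sqrt(outer(((seq_len(nr) - cx) * sp[1])^2,
                   ((seq_len(nc) - cy) * sp[2])^2, "+"))
  fov <- spec$shape * sp[1:2]
  body_r <- min(fov) / 2 - max(sp[1:2])
  body <- rr <= body_r

  # lateral lung fields, carved out wherever heart structures reach
  lung_centers <- c(cy - 0.33 * nc, cy + 0.33 * nc)
  lung <- matrix(FALSE, nr, nc)
  for (lc in lung_centers) {
    lr <- sqrt(outer(((seq_len(nr) - cx) * sp[1])^2,
                     ((seq_len(nc) - lc) * sp[2])^2, "+"))
    lung <- lung | (lr <= 6)
  }
  lung <- lung & body

  background <- matrix(spec$hu$air, nr, nc)
  background[body] <- spec$hu$body
  background[lung] <- spec$hu$lung

  vol <- array(rep(background, nz), dim = c(nr, nc, nz))
  sac <- array(0L, dim = c(nr, nc, nz))
  eat <- array(0L, dim = c(nr, nc, nz))

  r_profile <- phantom_radius_profile(spec)
  min_thick <- 3 * max(sp[1:2])  # median-stability floor for the annulus
  heart_slices <- spec$pad + seq_len(spec$n_heart)

  for (i in seq_len(spec$n_heart)) {
    z <- heart_slices[i]
    r_z <- r_profile[i]
    slice <- background
    outer_ring <- rr <= r_z + spec$wall_mm + spec$paracardial_mm
    slice[outer_ring] <- spec$hu$paracardial
    slice[rr <= r_z + spec$wall_mm] <- spec$hu$wall
    interior <- rr <= r_z
    slice[interior] <- spec$hu$blood

    eat_sl <- matrix(FALSE, nr, nc)
    if (any(interior)) {
      if (spec$eat_mode == "annulus") {
        thick <- max(r_z * (1 - sqrt(1 - spec$eat_fraction)), min_thick)
        r_in <- max(r_z - thick, 0)
        eat_sl <- interior & (rr > r_in)
      } else {
        n_blobs <- max(1L, round(spec$eat_fraction * 8))
        for (b in seq_len(n_blobs)) {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0.4, 0.9) * r_z
          br <- cx + rad * cos(ang) / sp[1]
          bc <- cy + rad * sin(ang) / sp[2]
          brad <- stats::runif(1, 0.15, 0.3) * r_z
          bd <- sqrt(outer(((seq_len(nr) - br) * sp[1])^2,
                           ((seq_len(nc) - bc) * sp[2])^2, "+"))
          eat_sl <- eat_sl | (bd <= brad)
        }
        eat_sl <- eat_sl & interior
      }
      slice[eat_sl] <- draw_eat_hu(sum(eat_sl))
    }

    vol[, , z] <- slice
    sac[, , z] <- interior
    eat[, , z] <- eat_sl
  }

  volume <- ct_volume(vol, spacing = sp,
                      scan_id = sprintf("phantom-%d", as.integer(seed)))

  if (spec$median_stable_mm > 0 && spec$eat_mode == "annulus") {
    st <- stabilise_phantom(volume, sac, eat, spec)
    volume <- st$volume; eat <- st$eat
  }

  if (spec$noise_sd > 0) {
    noisy <- volume$voxels + stats::rnorm(length(volume$voxels),
                                          sd = spec$noise_sd)
    volume <- ct_volume(round(noisy), spacing = sp,
                        scan_id = volume$scan_id)
  }

  sac_mask <- mask_volume(sac, spacing = sp, label = "sac_interior")
  eat_mask <- mask_volume(eat, spacing = sp, label = "eat")
  structure(
    list(volume = volume, sac = sac_mask, eat = eat_mask,
         extent = heart_extent(spec$pad + 1L, spec$pad + spec$n_heart),
         truth = list(eat_cm3 = eat_volume_cm3(eat_mask),
                      sac_cm3 = eat_volume_cm3(sac_mask)),
         spec = spec, seed = as.integer(seed)),
    class = "phantom"
  )
}

# Make the noise-free compartments a fixed point of the quantification
# median filter: any in-sac voxel whose filtered HU lands on the wrong
# side of the fat window is reassigned (with a matching HU draw) until
# the fat classification of the filtered and unfiltered volumes agree
# with the EAT truth mask. Converges in a couple of passes because each
# reassignment reinforces the local majority.
stabilise_phantom <- function(volume, sac, eat, spec, max_iter = 25L) {
  fw <- fat_window()
  for (iter in seq_len(max_iter)) {
    filtered <- median_filter_mm(volume, spec$median_stable_mm,
                                 quiet = TRUE)
    fat_cls <- (filtered$voxels >= fw$lo & filtered$voxels <= fw$hi) &
      sac == 1L
    mismatch_gain <- which(fat_cls & eat == 0L)
    mismatch_loss <- which(!fat_cls & eat == 1L)
    if (length(mismatch_gain) == 0L && length(mismatch_loss) == 0L) break
    v <- volume$voxels
    if (length(mismatch_gain)) {
      eat[mismatch_gain] <- 1L
      v[mismatch_gain] <- draw_eat_hu(length(mismatch_gain))
    }
    if (length(mismatch_loss)) {
      eat[mismatch_loss] <- 0L
      v[mismatch_loss] <- spec$hu$blood
    }
    volume <- ct_volume(v, spacing = volume$spacing,
                        scan_id = volume$scan_id)
  }
  list(volume = volume, eat = eat)
}

#' Generate a reproducible phantom cohort
#'
#' Draws per-phantom sac size, EAT fraction and noise level uniformly
#' within the given ranges and generates each phantom from its own
#' derived seed, so the whole cohort is a deterministic function of
#' `seed`.
#'
#' @param n cohort size (>= 1).
#' @param spec base [phantom_spec()]; the drawn parameters override its
#'   `r_max_mm`, `eat_fraction` and `noise_sd`.
#' @param r_max_range,eat_fraction_range,noise_sd_range sampling ranges.
#' @param seed integer cohort seed.
#' @return List of `n` phantoms (see [generate_phantom()]).
#' @export
generate_cohort <- function(n, spec = phantom_spec(),
                            r_max_range = c(10, 16),
                            eat_fraction_range = c(0.15, 0.35),
                            noise_sd_range = c(5, 15),
                            seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L, diff(r_max_range) >= 0, diff(eat_fraction_range) >= 0,
            diff(noise_sd_range) >= 0)
  set.seed(as.integer(seed))
  r_max <- stats::runif(n, r_max_range[1], r_max_range[2])
  frac <- stats::runif(n, eat_fraction_range[1], eat_fraction_range[2])
  noise <- stats::runif(n, noise_sd_range[1], noise_sd_range[2])
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    # rebuild through the constructor so drawn parameters are re-validated
    sp <- phantom_spec(shape = spec$shape, spacing = spec$spacing,
                       n_heart = spec$n_heart, pad = spec$pad,
                       r_max_mm = r_max[i], wall_mm = spec$wall_mm,
                       paracardial_mm = spec$paracardial_mm,
                       eat_fraction = frac[i], eat_mode = spec$eat_mode,
                       hu = spec$hu, noise_sd = noise[i],
                       median_stable_mm = spec$median_stable_mm)
    generate_phantom(sp, seed = seeds[i])
  })
}

#' Write a phantom to disk in clinical formats
#'
#' DICOM series for the HU volume, NIfTI for the two truth masks and a
#' small CSV with the analytic truth volumes.
#'
#' @param phantom a phantom from [generate_phantom()].
#' @param directory output directory.
#' @return Invisibly, the directory.
#' @export
write_phantom <- function(phantom, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_ct_series(phantom$volume, file.path(directory, "dicom"))
  save_mask(phantom$sac, file.path(directory, "sac_interior.nii.gz"))
  save_mask(phantom$eat, file.path(directory, "eat.nii.gz"))
  utils::write.csv(
    data.frame(scan_id = phantom$volume$scan_id,
               extent_bottom = phantom$extent$bottom,
               extent_top = phantom$extent$top,
               eat_cm3 = phantom$truth$eat_cm3,
               sac_cm3 = phantom$truth$sac_cm3),
    file.path(directory, "truth.csv"), row.names = FALSE)
  invisible(directory)
}

#' In-extent sac cross-sectional areas of a phantom
#'
#' Voxel-counted area (mm^2) of the sac-interior truth per heart slice;
#' used to check the always-increasing presentation property of the
#' bisected slab plan.
#'
#' @param phantom a phantom.
#' @return Numeric vector, one area per heart slice (bottom to top).
#' @export
phantom_sac_areas <- function(phantom) {
  idx <- phantom$extent$bottom:phantom$extent$top
  counts <- apply(phantom$sac$voxels[, , idx, drop = FALSE], 3, sum)
  counts * prod(phantom$spec$spacing[1:2])
}
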