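# Synthetic cardiac phantom: seeded short-axis-like subjects with a bright
# LV blood-pool disk, a darker myocardial annulus around it and an RV
# crescent hugging the annulus, on a noisy dark background. The generator
# reproduces the statistical structure the method relies on -- few labeled
# subjects, many unlabeled ones, smooth geometry change across slices and
# class-distinct intensities -- without claiming MR physics realism.

#' Phantom generator parameters
#'
#' Intensity means are on the `[0, 1]` scale; geometry is in pixels. The
#' defaults define the desk-scale study conditions: 64x64 slices, 5 slices
#' per subject, intensity means background 0.20 / MYO 0.35 / RV 0.70 /
#' LV 0.80 with noise sd 0.05, LV radius 6-9 px, myocardial thickness
#' 3-5 px, and radii shrinking towards the apex across the slice stack.
#'
#' @param size Image side length in pixels.
#' @param slices_per_subject Slices in each subject's stack.
#' @param intensities Named means for `bg`, `RV`, `MYO`, `LV`.
#' @param noise_sd Gaussian intensity noise sd.
#' @param lv_radius_range LV blood-pool radius range (base slice), px.
#' @param myo_thickness_range Annulus thickness range, px.
#' @param rv_scale_range RV crescent radius as a fraction of the annulus
#'   outer radius.
#' @param center_jitter Max per-subject displacement of the LV centre, px.
#' @param slice_jitter Max per-slice centre drift, px.
#' @param apex_scale Radial scale at the apex end of the stack (the base end
#'   is 1); radii interpolate linearly across slices.
#' @param spacing Physical voxel spacing `(row, col, slice)` in mm.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(size = 64L, slices_per_subject = 5L,
                           intensities = c(bg = 0.20, RV = 0.70,
                                           MYO = 0.35, LV = 0.80),
                           noise_sd = 0.05,
                           lv_radius_range = c(6, 9),
                           myo_thickness_range = c(3, 5),
                           rv_scale_range = c(0.8, 1.0),
                           center_jitter = 4, slice_jitter = 1,
                           apex_scale = 0.75,
                           spacing = c(1, 1, 1)) {
  stopifnot(size >= 16, slices_per_subject >= 1,
            all(intensities >= 0 & intensities <= 1),
            noise_sd >= 0, all(lv_radius_range > 0),
            all(myo_thickness_range > 0))
  p <- structure(list(size = as.integer(size),
                      slices_per_subject = as.integer(slices_per_subject),
                      intensities = intensities, noise_sd = noise_sd,
                      lv_radius_range = lv_radius_range,
                      myo_thickness_range = myo_thickness_range,
                      rv_scale_range = rv_scale_range,
                      center_jitter = center_jitter,
                      slice_jitter = slice_jitter,
                      apex_scale = apex_scale, spacing = spacing),
                 class = "phantom_params")
  # the myocardial annulus must fit inside the image at every jitter (the RV
  # crescent may touch the border on extreme draws, as at the edge of a FOV)
  myo_max <- max(lv_radius_range) + max(myo_thickness_range)
  extent <- myo_max + center_jitter + slice_jitter
  if (extent >= size / 2) {
    stop("infeasible phantom geometry: structures of extent ", extent,
         " px cannot fit in a ", size, "x", size, " image")
  }
  p
}

phantom_slice <- function(p, center, lv_r, myo_r, rv_r, rv_dir) {
  n <- p$size
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  d_lv <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  c_rv <- center + rv_dir * myo_r
  d_rv <- sqrt((rows - c_rv[1])^2 + (cols - c_rv[2])^2)
  mask <- matrix(0L, n, n)
  mask[d_rv <= rv_r & d_lv > myo_r] <- 1L  # RV crescent outside the annulus
  mask[d_lv <= myo_r] <- 2L                # myocardium annulus
  mask[d_lv <= lv_r] <- 3L                 # LV blood pool
  means <- p$intensities[c("bg", "RV", "MYO", "LV")]
  img <- matrix(means[mask + 1L], n, n)
  img <- img + matrix(stats::rnorm(n * n, 0, p$noise_sd), n, n)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

#' Generate one synthetic phantom subject
#'
#' Geometry (LV centre, radii, RV direction) is drawn once per subject;
#' radii scale linearly from `apex_scale` at the first slice to 1 at the
#' last, with a small per-slice centre drift, emulating short-axis
#' apex-to-base variation. The same seed reproduces the subject
#' bit-identically.
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed.
#' @param id Subject identifier string.
#' @return A subject: list with `id`, `images`, `masks`, `spacing`, `phases`.
#' @export
generate_subject <- function(params = phantom_params(), seed = 1L,
                             id = sprintf("phantom%03d", seed)) {
  with_seed(seed, {
    n <- params$size
    ctr0 <- c(n / 2, n / 2) +
      stats::runif(2, -params$center_jitter, params$center_jitter)
    lv_r0 <- stats::runif(1, params$lv_radius_range[1],
                          params$lv_radius_range[2])
    myo_th <- stats::runif(1, params$myo_thickness_range[1],
                           params$myo_thickness_range[2])
    rv_scale <- stats::runif(1, params$rv_scale_range[1],
                             params$rv_scale_range[2])
    ang <- pi + stats::runif(1, -pi / 9, pi / 9)  # RV roughly to the left
    rv_dir <- c(sin(ang), cos(ang))
    nsl <- params$slices_per_subject
    images <- vector("list", nsl)
    masks <- vector("list", nsl)
    for (k in seq_len(nsl)) {
      f <- if (nsl == 1) 1 else
        params$apex_scale + (1 - params$apex_scale) * (k - 1) / (nsl - 1)
      ctr <- ctr0 + stats::runif(2, -params$slice_jitter, params$slice_jitter)
      sl <- phantom_slice(params, ctr, f * lv_r0, f * (lv_r0 + myo_th),
                          f * rv_scale * (lv_r0 + myo_th), rv_dir)
      images[[k]] <- sl$image
      masks[[k]] <- sl$mask
    }
    list(id = id, images = images, masks = masks, spacing = params$spacing,
         phases = rep("ED", nsl))
  })
}

#' Generate a phantom dataset
#'
#' Subjects are generated from independent per-subject seeds derived from
#' the master seed, so the dataset is reproducible and individual subjects
#' are independent draws.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param params A [phantom_params()].
#' @param seed Master seed.
#' @return List of subjects suitable for [make_split()].
#' @export
generate_dataset <- function(n_subjects, params = phantom_params(),
                             seed = 1L) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    generate_subject(params, seed = seed_for(seed, 21L, i),
                     id = sprintf("phantom%03d", i))
  })
}

#' Write a phantom dataset in the ACDC-style NIfTI layout
#'
#' Each subject becomes a directory `<id>/` containing
#' `<id>_frame01.nii.gz` and (unless suppressed) `<id>_frame01_gt.nii.gz`,
#' readable by [load_acdc_subject()], so the full pipeline can be exercised
#' through the real I/O path.
#'
#' @param subjects List of subjects from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @param with_gt Write ground-truth volumes (default yes).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(subjects, dir, with_gt = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (su in subjects) {
    sdir <- file.path(dir, su$id)
    dir.create(sdir, showWarnings = FALSE)
    d <- dim(su$images[[1]])
    vol <- array(0, dim = c(d, length(su$images)))
    for (k in seq_along(su$images)) vol[, , k] <- su$images[[k]]
    img <- RNifti::asNifti(vol, pixdim = su$spacing)
    RNifti::writeNifti(img, file.path(sdir, paste0(su$id, "_frame01.nii.gz")))
    if (with_gt && !is.null(su$masks)) {
      gt <- array(0L, dim = c(d, length(su$masks)))
      for (k in seq_along(su$masks)) gt[, , k] <- su$masks[[k]]
      gti <- RNifti::asNifti(gt, pixdim = su$spacing)
      RNifti::writeNifti(gti,
                         file.path(sdir, paste0(su$id, "_frame01_gt.nii.gz")))
    }
  }
  invisible(dir)
}
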