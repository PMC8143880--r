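# Standard train-time augmentation: affine (rotation / scale / shear) and
# random intensity shift. The identical geometric transform is applied to the
# image (bilinear) and its mask (nearest neighbour); intensity changes touch
# the image only.

warp_sample <- function(img, mask = NULL, angle = 0, scale = 1, shear = 0) {
  th <- angle * pi / 180
  sh <- shear * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- diag(c(scale, scale))
  H <- matrix(c(1, 0, tan(sh), 1), 2, 2)
  M <- R %*% S %*% H
  Minv <- solve(M)
  out_img <- cpp_warp_affine(img, Minv, c(0, 0), fill = 0, nearest = FALSE)
  out_mask <- NULL
  if (!is.null(mask)) {
    out_mask <- cpp_warp_affine(mask, Minv, c(0, 0), fill = 0, nearest = TRUE)
    storage.mode(out_mask) <- "integer"
  }
  list(image = out_img, mask = out_mask)
}

#' Randomly augment one training sample
#'
#' Draws a rotation angle, isotropic scale, shear and intensity shift from
#' the configured ranges, applies the same geometric transform to image
#' (bilinear interpolation) and mask (nearest neighbour, so no new label
#' values can appear), shifts the image intensities and re-clips to `[0, 1]`.
#' With all ranges zero (and scale range `c(1, 1)`) the sample is returned
#' unchanged.
#'
#' @param img Image matrix in `[0, 1]`.
#' @param mask Optional integer label mask of the same shape.
#' @param ranges List with `rotate` (max degrees), `scale` (length-2 range),
#'   `shear` (max degrees) and `intensity` (max absolute shift).
#' @param seed Optional integer for an isolated RNG stream.
#' @return List with `image` and `mask` (NULL if none given).
#' @export
augment_sample <- function(img, mask = NULL,
                           ranges = list(rotate = 15, scale = c(0.9, 1.1),
                                         shear = 0, intensity = 0.1),
                           seed = NULL) {
  draw <- function() {
    list(angle = stats::runif(1, -ranges$rotate, ranges$rotate),
         scale = stats::runif(1, ranges$scale[1], ranges$scale[2]),
         shear = stats::runif(1, -ranges$shear, ranges$shear),
         shift = stats::runif(1, -ranges$intensity, ranges$intensity))
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  w <- warp_sample(img, mask, angle = d$angle, scale = d$scale,
                   shear = d$shear)
  w$image <- pmin(pmax(w$image + d$shift, 0), 1)
  w
}
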