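# Feature-space perturbations (spatial dropout, Gaussian noise) and the
# input-space cut-and-mix perturbation.

#' Feature perturbation configuration
#'
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   absolute feature units (default 0.1).
#' @param dropout_range Interval the spatial dropout rate is drawn from
#'   uniformly per forward pass (default `c(0.10, 0.40)`).
#' @return A `perturb_config` list.
#' @export
perturb_config <- function(noise_sigma = 0.1, dropout_range = c(0.10, 0.40)) {
  stopifnot(noise_sigma >= 0, length(dropout_range) == 2,
            dropout_range[1] >= 0, dropout_range[2] <= 1,
            dropout_range[1] <= dropout_range[2])
  structure(list(noise_sigma = noise_sigma, dropout_range = dropout_range),
            class = "perturb_config")
}

#' Additive Gaussian noise perturbation `P_N`
#'
#' @param f Feature array (any shape).
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Optional integer; draws come from an isolated RNG stream.
#' @return Perturbed array of identical shape.
#' @export
feature_noise <- function(f, sigma, seed = NULL) {
  if (sigma < 0) stop("noise sigma must be nonnegative")
  draw <- function() array(stats::rnorm(length(f), 0, sigma), dim = dim(f))
  eps <- if (is.null(seed)) draw() else with_seed(seed, draw())
  f + eps
}

#' Spatial dropout perturbation `P_D`
#'
#' Draws a rate `r` uniformly from `rate_range`, then zeroes
#' `round(r * h * w)` spatial positions chosen uniformly without replacement
#' -- the same positions across every channel. Survivors are not rescaled:
#' this is a consistency-training perturbation, not train-time
#' regularisation.
#'
#' @param f Feature array `(h, w, c)` (a matrix is one channel).
#' @param rate_range Dropout-rate interval within `[0, 1]`.
#' @param seed Optional integer for an isolated RNG stream.
#' @param return_mask Also attach the binary spatial mask as attribute
#'   `"mask"` (used by the training backward pass).
#' @return Perturbed array of identical shape.
#' @export
feature_dropout <- function(f, rate_range = c(0.10, 0.40), seed = NULL,
                            return_mask = FALSE) {
  f <- as_feature(f)
  d <- dim(f)
  if (length(f) == 0) stop("empty feature map")
  stopifnot(length(rate_range) == 2, rate_range[1] >= 0, rate_range[2] <= 1)
  draw <- function() {
    r <- stats::runif(1, rate_range[1], rate_range[2])
    nz <- round(r * d[1] * d[2])
    pos <- if (nz > 0) sample.int(d[1] * d[2], nz) else integer(0)
    pos
  }
  pos <- if (is.null(seed)) draw() else with_seed(seed, draw())
  mask <- matrix(1, d[1], d[2])
  mask[pos] <- 0
  out <- f * as.vector(mask)
  if (return_mask) attr(out, "mask") <- mask
  out
}

#' Cut-and-mix block specification
#'
#' Both images are split into a fixed 2x2 grid of equal blocks; `k` blocks
#' (one or two) at the given positions are exchanged between the two images
#' at corresponding positions.
#'
#' @param positions Distinct block indices in `0:3` (0 = top-left,
#'   1 = top-right, 2 = bottom-left, 3 = bottom-right).
#' @return A `cutmix_spec` list with fields `k` and `positions`.
#' @export
cutmix_spec <- function(positions) {
  positions <- as.integer(positions)
  if (length(positions) < 1 || length(positions) > 2 ||
      anyDuplicated(positions) || any(positions < 0 | positions > 3)) {
    stop("positions must be 1 or 2 distinct block indices in 0:3")
  }
  structure(list(k = length(positions), positions = positions),
            class = "cutmix_spec")
}

random_cutmix_spec <- function() {
  k <- sample(1:2, 1)
  cutmix_spec(sample(0:3, k))
}

block_index <- function(pos, h, w) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  rows <- if (pos %in% c(0L, 1L)) seq_len(h2) else h2 + seq_len(h2)
  cols <- if (pos %in% c(0L, 2L)) seq_len(w2) else w2 + seq_len(w2)
  list(rows = rows, cols = cols)
}

#' Cut-and-mix input perturbation `P_C`
#'
#' Exchanges the selected 2x2-grid blocks between two images, and applies the
#' identical exchange to their label masks when given. Applying the same spec
#' twice restores the originals.
#'
#' @param img_a,img_b Image matrices of identical even dimensions.
#' @param spec A [cutmix_spec()].
#' @param mask_a,mask_b Optional label masks (both or neither).
#' @return List with `img_a`, `img_b` and, when masks were supplied,
#'   `mask_a`, `mask_b`.
#' @export
cut_and_mix <- function(img_a, img_b, spec, mask_a = NULL, mask_b = NULL) {
  if (!identical(dim(img_a), dim(img_b))) {
    stop("images must share the same shape")
  }
  h <- nrow(img_a); w <- ncol(img_a)
  if (h %% 2 != 0 || w %% 2 != 0) {
    stop("cut-and-mix needs even image dimensions, got ", h, "x", w)
  }
  if (is.null(mask_a) != is.null(mask_b)) {
    stop("masks must be supplied for both images or neither")
  }
  if (!is.null(mask_a) &&
      (!identical(dim(mask_a), dim(img_a)) ||
       !identical(dim(mask_b), dim(img_b)))) {
    stop("masks must share the images' shape")
  }
  swap <- function(a, b) {
    for (pos in spec$positions) {
      bi <- block_index(pos, h, w)
      tmp <- a[bi$rows, bi$cols]
      a[bi$rows, bi$cols] <- b[bi$rows, bi$cols]
      b[bi$rows, bi$cols] <- tmp
    }
    list(a = a, b = b)
  }
  im <- swap(img_a, img_b)
  out <- list(img_a = im$a, img_b = im$b)
  if (!is.null(mask_a)) {
    mm <- swap(mask_a, mask_b)
    out$mask_a <- mm$a
    out$mask_b <- mm$b
  }
  out
}

#' Build a cut-and-mixed copy of a sample set
#'
#' Samples are randomly paired within the set (labeled with labeled,
#' unlabeled with unlabeled -- the caller passes a single pool) and each pair
#' receives an independent random [cutmix_spec()]. An odd leftover sample
#' passes through unmixed, so the output has exactly as many samples as the
#' input.
#'
#' @param samples List of samples, each a list with `image` and optionally
#'   `mask`.
#' @param seed Optional integer for an isolated RNG stream.
#' @return List of mixed samples, same length as `samples`.
#' @export
make_mixed_set <- function(samples, seed = NULL) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples to pair for cut-and-mix")
  run <- function() {
    ord <- sample.int(n)
    out <- samples
    n_pairs <- n %/% 2
    for (p in seq_len(n_pairs)) {
      i <- ord[2 * p - 1]; j <- ord[2 * p]
      spec <- random_cutmix_spec()
      a <- samples[[i]]; b <- samples[[j]]
      mixed <- cut_and_mix(a$image, b$image, spec, a$mask, b$mask)
      out[[i]]$image <- mixed$img_a
      out[[j]]$image <- mixed$img_b
      if (!is.null(a$mask)) {
        out[[i]]$mask <- mixed$mask_a
        out[[j]]$mask <- mixed$mask_b
      }
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
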