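# Shared fixtures and independent oracles used across the suite.

# Brute-force Dice: plain set arithmetic over coordinate pairs.
bf_dice <- function(X, Y) {
  nx <- sum(X != 0); ny <- sum(Y != 0)
  if (nx == 0 && ny == 0) return(1)
  if (nx == 0 || ny == 0) return(0)
  2 * sum(X != 0 & Y != 0) / (nx + ny)
}

# Brute-force Hausdorff: O(|X| * |Y|) double-max over explicit point sets.
bf_hausdorff <- function(X, Y, spacing = rep(1, 3)) {
  cx <- which(X != 0, arr.ind = TRUE)
  cy <- which(Y != 0, arr.ind = TRUE)
  if (is.vector(cx)) cx <- matrix(cx, ncol = 1)
  sp <- spacing[seq_len(ncol(cx))]
  cx <- sweep(cx, 2, sp, `*`)
  cy <- sweep(cy, 2, sp, `*`)
  dmin_to <- function(A, B) {
    apply(A, 1, function(a) {
      min(sqrt(colSums((t(B) - a)^2)))
    })
  }
  max(max(dmin_to(cx, cy)), max(dmin_to(cy, cx)))
}

# Tiny backbone config for fast training tests (32x32 inputs, depth 2).
tiny_cfg <- function(kind = "ghost", upsample = "bilinear") {
  backbone_config(depth = 2L, base_width = 4L, num_classes = 4L,
                  block_kind = kind, upsample_kind = upsample,
                  input_size = c(32L, 32L))
}

# Small phantom parameters matching the tiny network's 32x32 input.
tiny_phantom <- function() {
  phantom_params(size = 32L, slices_per_subject = 2L,
                 lv_radius_range = c(4, 5), myo_thickness_range = c(2, 3),
                 center_jitter = 2, slice_jitter = 1)
}

tiny_split <- function(n_subjects = 4, K = 1, test_count = 1, seed = 11) {
  subjects <- generate_dataset(n_subjects, tiny_phantom(), seed = seed)
  make_split(subjects, K = K, test_count = test_count, seed = seed)
}

# Copy the supervised decoder's weights into the auxiliary decoders so all
# three paths compute the same function.
sync_decoders <- function(cc) {
  p <- net_params(cc)
  p$dec_D <- p$dec_S
  p$dec_N <- p$dec_S
  net_set_params(cc, p)
}

expect_same_params <- function(a, b, tol = 0) {
  expect_lte(ghostseg:::par_max_abs_diff(a, b), tol)
}
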