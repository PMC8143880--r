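# Feature-space and input-space perturbation contracts.

test_that("feature noise: zero-sigma identity, determinism, calibrated sd", {
  f <- array(runif(10 * 10 * 3), c(10, 10, 3))
  expect_identical(feature_noise(f, 0, seed = 1), f)
  expect_identical(feature_noise(f, 0.2, seed = 5),
                   feature_noise(f, 0.2, seed = 5))
  expect_false(identical(feature_noise(f, 0.2, seed = 5),
                         feature_noise(f, 0.2, seed = 6)))
  expect_error(feature_noise(f, -0.1), "nonnegative")

  big <- array(0, c(100, 100, 10))  # 1e5 elements
  eps <- feature_noise(big, 0.1, seed = 2) - big
  expect_lt(abs(stats::sd(eps) - 0.1), 0.005)
  expect_lt(abs(mean(eps)), 3 * 0.1 / sqrt(length(big)))
})

test_that("feature dropout zeroes the same spatial positions in every
          channel, at the drawn rate, without rescaling survivors", {
  f <- array(runif(8 * 8 * 5) + 0.5, c(8, 8, 5))  # strictly positive
  expect_identical(feature_dropout(f, c(0, 0), seed = 1), f)

  out <- feature_dropout(f, c(0.25, 0.25), seed = 3)
  zero_pos <- out[, , 1] == 0
  expect_identical(sum(zero_pos), 16L)  # round(0.25 * 64)
  for (ch in 2:5) expect_identical(out[, , ch] == 0, zero_pos)
  # survivors untouched (no 1/(1-r) rescaling)
  expect_identical(out[, , 2][!zero_pos], f[, , 2][!zero_pos])

  expect_identical(feature_dropout(f, c(0.1, 0.4), seed = 9),
                   feature_dropout(f, c(0.1, 0.4), seed = 9))
  # zero fraction always equals round(r h w) / (h w) for drawn r
  for (s in 1:20) {
    o <- feature_dropout(f, c(0.1, 0.4), seed = s)
    nz <- sum(o[, , 1] == 0)
    expect_gte(nz, round(0.1 * 64))
    expect_lte(nz, round(0.4 * 64))
  }
  expect_error(feature_dropout(array(numeric(0), c(0, 0, 0))), "empty")
})

test_that("cut-and-mix swaps the stated blocks and nothing else", {
  a <- matrix(0, 4, 4)
  b <- matrix(1, 4, 4)
  r <- cut_and_mix(a, b, cutmix_spec(0L))
  want_a <- matrix(0, 4, 4); want_a[1:2, 1:2] <- 1
  expect_identical(r$img_a, want_a)
  expect_identical(r$img_b, 1 - want_a)

  # swap of equal images is the identity
  r2 <- cut_and_mix(a, a, cutmix_spec(c(1L, 3L)))
  expect_identical(r2$img_a, a)
  expect_identical(r2$img_b, a)

  expect_error(cut_and_mix(a, matrix(0, 4, 6), cutmix_spec(0L)), "shape")
  expect_error(cut_and_mix(matrix(0, 3, 3), matrix(0, 3, 3),
                           cutmix_spec(0L)), "even")
  expect_error(cut_and_mix(a, b, cutmix_spec(0L), mask_a = a), "both")
  expect_error(cutmix_spec(c(0L, 0L)))
  expect_error(cutmix_spec(c(0L, 1L, 2L)))
  expect_error(cutmix_spec(4L))
})

test_that("cut-and-mix is an involution and conserves the pixel multiset,
          identically on images and masks", {
  set.seed(10)
  for (i in 1:100) {
    h <- 2 * sample(2:8, 1); w <- 2 * sample(2:8, 1)
    a <- matrix(rnorm(h * w), h, w)
    b <- matrix(rnorm(h * w), h, w)
    ma <- matrix(sample(0:3, h * w, TRUE), h, w)
    mb <- matrix(sample(0:3, h * w, TRUE), h, w)
    k <- sample(1:2, 1)
    spec <- cutmix_spec(sample(0:3, k))
    r <- cut_and_mix(a, b, spec, ma, mb)
    # conservation of the joint pixel multiset
    expect_identical(sort(c(r$img_a, r$img_b)), sort(c(a, b)))
    expect_identical(tabulate(c(r$mask_a, r$mask_b) + 1, 4),
                     tabulate(c(ma, mb) + 1, 4))
    # involution restores the originals
    r2 <- cut_and_mix(r$img_a, r$img_b, spec, r$mask_a, r$mask_b)
    expect_identical(r2$img_a, a)
    expect_identical(r2$img_b, b)
    expect_identical(r2$mask_a, ma)
    expect_identical(r2$mask_b, mb)
    # the same positions moved in image and mask
    moved_img <- r$img_a != a
    moved_mask_possible <- ma != mb
    expect_true(all(r$mask_a[!moved_img & !moved_mask_possible] ==
                    ma[!moved_img & !moved_mask_possible]))
  }
})

test_that("make_mixed_set preserves size and the global pixel multiset", {
  set.seed(11)
  samples <- lapply(1:10, function(i) {
    list(image = matrix(rnorm(16), 4, 4),
         mask = matrix(sample(0:3, 16, TRUE), 4, 4))
  })
  mixed <- make_mixed_set(samples, seed = 4)
  expect_length(mixed, 10)
  all_px <- function(ss) sort(unlist(lapply(ss, `[[`, "image")))
  expect_identical(all_px(mixed), all_px(samples))
  expect_identical(make_mixed_set(samples, seed = 4), mixed)
  expect_false(identical(make_mixed_set(samples, seed = 5), mixed))

  # odd pool: the leftover passes through unmixed, size preserved
  odd <- samples[1:5]
  modd <- make_mixed_set(odd, seed = 6)
  expect_length(modd, 5)
  expect_identical(all_px(modd), all_px(odd))

  expect_error(make_mixed_set(samples[1], seed = 1), "at least 2")
})
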