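# Dice and Hausdorff metrics against independent brute-force oracles.

test_that("dice: identities, conventions and the worked overlap", {
  m <- matrix(0, 4, 4)
  X <- m; X[1:2, 1:2] <- 1
  expect_equal(dice(X, X), 1)
  Y <- m; Y[3:4, 3:4] <- 1
  expect_equal(dice(X, Y), 0)
  # two 2x2 squares overlapping in a 2x1 strip: 2*2/(4+4) = 0.5
  Z <- m; Z[1:2, 2:3] <- 1
  expect_equal(dice(X, Z), 0.5)
  # conventions for empty regions
  expect_equal(dice(m, m), 1)
  expect_equal(dice(X, m), 0)
  # the printed-form variant uses the union in the denominator
  expect_equal(dice(X, Z, variant = "printed"), 2 * 2 / 6)
  expect_error(dice(X, matrix(0, 3, 3)), "grid")
})

test_that("hausdorff: worked 3-4-5 value, spacing linearity, empty regions", {
  X <- matrix(0, 6, 6); X[1, 1] <- 1
  Y <- matrix(0, 6, 6); Y[4, 5] <- 1
  expect_equal(hausdorff(X, Y), 5)
  expect_equal(hausdorff(X, X), 0)
  expect_equal(hausdorff(X, Y, spacing = c(2, 2)), 10)
  expect_warning(h <- hausdorff(X, matrix(0, 6, 6)), "empty")
  expect_true(is.na(h))
})

test_that("dice and hausdorff match brute-force oracles on random masks,
          symmetrically", {
  set.seed(50)
  for (i in 1:60) {
    X <- matrix(rbinom(64, 1, 0.3), 8, 8)
    Y <- matrix(rbinom(64, 1, 0.3), 8, 8)
    expect_equal(dice(X, Y), bf_dice(X, Y))
    expect_equal(dice(Y, X), dice(X, Y))
    # Dice identity via the symmetric difference
    if (sum(X) + sum(Y) > 0) {
      expect_equal(dice(X, Y),
                   1 - sum(xor(X, Y)) / (sum(X) + sum(Y)),
                   tolerance = 1e-12)
    }
    if (sum(X) > 0 && sum(Y) > 0) {
      expect_equal(hausdorff(X, Y), bf_hausdorff(X, Y), tolerance = 1e-12)
      expect_equal(hausdorff(Y, X), hausdorff(X, Y))
    }
  }
  # anisotropic 3D spacing agrees with the oracle too
  X <- array(rbinom(128, 1, 0.4), c(4, 4, 8))
  Y <- array(rbinom(128, 1, 0.4), c(4, 4, 8))
  sp <- c(1.5, 1.5, 3)
  expect_equal(hausdorff(X, Y, spacing = sp), bf_hausdorff(X, Y, sp),
               tolerance = 1e-12)
})

test_that("evaluate_model: oracle predictor is perfect, all-background
          predictor scores zero, report matches hand computation", {
  # images encode their masks exactly, so a decoding predictor is an oracle
  mk_subject <- function(id, seed) {
    set.seed(seed)
    masks <- lapply(1:2, function(k) {
      m <- matrix(0L, 8, 8)
      m[2:3, 2:3] <- 3L; m[4:5, 2:3] <- 2L; m[2:3, 5:6] <- 1L
      if (k == 2) m <- m[, c(2:8, 1)]  # shift to vary across slices
      m
    })
    list(id = id, images = lapply(masks, function(m) m / 3),
         masks = masks, spacing = c(1, 1, 1), phases = c("ED", "ES"))
  }
  subs <- list(mk_subject("s1", 1), mk_subject("s2", 2))
  oracle <- function(img) {
    m <- round(img * 3)
    storage.mode(m) <- "integer"
    m
  }
  rep <- evaluate_model(NULL, subs, predict_fn = oracle)
  expect_true(all(rep$per_subject$dice == 100))
  expect_true(all(rep$per_subject$hausdorff == 0))

  bg <- function(img) matrix(0L, nrow(img), ncol(img))
  w <- capture_warnings(rep0 <- evaluate_model(NULL, subs, predict_fn = bg))
  expect_true(any(grepl("empty region", w)))
  expect_true(all(rep0$per_subject$dice == 0))
  expect_true(all(is.na(rep0$per_subject$hausdorff)))

  # constant plausible predictor versus hand-computed per-subject stacks
  const <- function(img) {
    m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 3L
    m
  }
  repc <- suppressWarnings(evaluate_model(NULL, subs, predict_fn = const))
  for (su in subs) {
    gt <- array(0L, c(8, 8, 2))
    pr <- array(0L, c(8, 8, 2))
    for (k in 1:2) {
      gt[, , k] <- su$masks[[k]]
      pr[, , k] <- const(su$images[[k]])
    }
    want_d <- 100 * bf_dice(pr == 3, gt == 3)
    want_h <- bf_hausdorff(pr == 3, gt == 3)
    got <- repc$per_subject[repc$per_subject$subject == su$id &
                            repc$per_subject$structure == "LV", ]
    expect_equal(got$dice, want_d, tolerance = 1e-12)
    expect_equal(got$hausdorff, want_h, tolerance = 1e-12)
  }
  # summary means over subjects
  lv <- repc$per_subject[repc$per_subject$structure == "LV", ]
  expect_equal(repc$summary$dice[repc$summary$structure == "LV"],
               mean(lv$dice))
})

test_that("evaluation is invariant to slice order within a subject", {
  su <- generate_subject(tiny_phantom(), seed = 60, id = "p")
  su_rev <- su
  su_rev$images <- rev(su_rev$images)
  su_rev$masks <- rev(su_rev$masks)
  oracle_like <- function(img) {
    m <- matrix(0L, nrow(img), ncol(img))
    m[img > 0.5] <- 3L
    m
  }
  r1 <- suppressWarnings(evaluate_model(NULL, list(su),
                                        predict_fn = oracle_like))
  r2 <- suppressWarnings(evaluate_model(NULL, list(su_rev),
                                        predict_fn = oracle_like))
  expect_equal(r1$per_subject$dice, r2$per_subject$dice)
  expect_equal(r1$per_subject$hausdorff, r2$per_subject$hausdorff)
})
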