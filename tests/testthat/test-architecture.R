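# Ghost module and backbone architecture contracts.

test_that("ghost module output shape, identity group and degenerate cases", {
  set.seed(1)
  cfg <- ghost_config(6, 16, ratio = 4)
  w <- ghost_init(cfg)
  x <- array(rnorm(10 * 12 * 6), c(10, 12, 6))
  out <- ghost_forward(x, cfg, w)
  expect_equal(dim(out), c(10, 12, 16))
  # the first b/s channels are the intrinsic maps themselves
  fp <- ghostseg:::conv_fwd(w$primary, x, relu = TRUE)
  expect_equal(out[, , 1:4], fp)

  # all-zero weights give an all-zero output (linear block)
  cfg0 <- ghost_config(6, 16, ratio = 4, use_act = FALSE, use_bias = FALSE)
  w0 <- ghost_init(cfg0)
  w0$primary$W[] <- 0
  for (j in seq_along(w0$cheap)) w0$cheap[[j]]$W[] <- 0
  expect_true(all(ghost_forward(x, cfg0, w0) == 0))

  # indivisible channel count is a configuration error
  expect_error(ghost_config(4, 10, ratio = 4), "divisible")
  # channel mismatch is a shape error
  expect_error(ghost_forward(array(0, c(4, 4, 3)), cfg, w), "channels")
})

test_that("ghost parameter count matches closed form and enumeration", {
  # bias-free closed form: 9*a*(b/s) + (s-1)*(b/s)*9
  cfg <- ghost_config(64, 64, ratio = 4, use_bias = FALSE)
  expect_identical(ghost_param_count(cfg), 9648L)
  w <- ghost_init(cfg)
  n_weights <- length(w$primary$W) +
    sum(vapply(w$cheap, function(l) length(l$W), numeric(1)))
  expect_identical(as.integer(n_weights), 9648L)
  # the standard conv it replaces has 9*64*64 = 36864 weights
  expect_identical(9L * 64L * 64L, 36864L)

  # counts match enumeration of the trainable leaves for random shapes,
  # with bias terms and with affine norm
  enum_ghost <- function(w) {
    ghostseg:::par_count(list(ghostseg:::layer_params(w$primary),
                              lapply(w$cheap, ghostseg:::layer_params)))
  }
  set.seed(42)
  for (i in 1:20) {
    s <- sample(c(1L, 2L, 4L, 8L), 1)
    a <- sample(1:32, 1)
    b <- s * sample(1:16, 1)
    nrm <- sample(c(TRUE, FALSE), 1)
    cfg <- ghost_config(a, b, ratio = s, use_norm = nrm)
    expect_identical(ghost_param_count(cfg),
                     as.integer(enum_ghost(ghost_init(cfg))))
  }
})

test_that("s = 1 ghost block equals a standard convolution", {
  set.seed(2)
  cfg1 <- ghost_config(5, 7, ratio = 1)
  expect_identical(ghost_param_count(cfg1), 9L * 5L * 7L + 7L)
  w <- ghost_init(cfg1)
  x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  conv <- list(type = "conv", k = 3L, pad = 1L, W = w$primary$W,
               bias = w$primary$bias)
  expect_equal(ghost_forward(x, cfg1, w),
               ghostseg:::conv_fwd(conv, x, relu = TRUE))
})

test_that("backbone maps a slice to a normalized probability map", {
  for (kind in c("standard", "ghost")) {
    for (up in c("bilinear", "transposed_conv")) {
      cfg <- tiny_cfg(kind, up)
      net <- build_backbone(cfg, seed = 3)
      img <- matrix(runif(32 * 32), 32, 32)
      p <- predict_prob(net, img)
      expect_equal(dim(p), c(32, 32, 4))
      expect_true(all(p >= 0))
      sums <- p[, , 1] + p[, , 2] + p[, , 3] + p[, , 4]
      expect_lt(max(abs(sums - 1)), 1e-5)
    }
  }
  # input size not divisible by 2^(depth-1) is a shape error
  net <- build_backbone(tiny_cfg(), seed = 3)
  expect_error(predict_prob(net, matrix(0, 31, 31)), "divisible")
})

test_that("assembly shares one encoder across three independent decoders", {
  cfg <- tiny_cfg("ghost")
  cc <- build_cc_net(cfg, seed = 4)
  p <- net_params(cc)
  n_enc <- ghostseg:::par_count(p$encoder)
  n_dec <- ghostseg:::par_count(p$dec_S)
  expect_identical(ghostseg:::par_count(p$dec_D), n_dec)
  expect_identical(ghostseg:::par_count(p$dec_N), n_dec)
  expect_identical(count_params(cc), as.integer(n_enc + 3 * n_dec))
  expect_identical(count_params(test_time_net(cc)),
                   as.integer(n_enc + n_dec))
  # independent weights: decoders differ at initialisation
  expect_gt(ghostseg:::par_max_abs_diff(p$dec_S, p$dec_D), 0)
})

test_that("forward_paths: zero perturbation with synced decoders is exact,
          fixed seeds reproduce bit-identically", {
  cfg <- tiny_cfg("ghost")
  cc <- sync_decoders(build_cc_net(cfg, seed = 5))
  img <- matrix(runif(32 * 32), 32, 32)
  r0 <- forward_paths(cc, img, seed = 9, perturb = FALSE)
  expect_identical(r0$p_S, r0$p_D)
  expect_identical(r0$p_S, r0$p_N)

  # zero-magnitude perturbations behave like no perturbation
  cc$perturb <- perturb_config(noise_sigma = 0, dropout_range = c(0, 0))
  rz <- forward_paths(cc, img, seed = 9, perturb = TRUE)
  expect_identical(rz$p_S, rz$p_D)
  expect_identical(rz$p_S, rz$p_N)

  cc$perturb <- perturb_config()
  r1 <- forward_paths(cc, img, seed = 7)
  r2 <- forward_paths(cc, img, seed = 7)
  expect_identical(r1$p_D, r2$p_D)
  expect_identical(r1$p_N, r2$p_N)
  r3 <- forward_paths(cc, img, seed = 8)
  expect_false(identical(r1$p_D, r3$p_D))
})

test_that("analytic parameter counts equal enumerated weights", {
  for (kind in c("standard", "ghost")) {
    for (up in c("bilinear", "transposed_conv")) {
      cfg <- backbone_config(depth = 3, base_width = 4, block_kind = kind,
                             upsample_kind = up, input_size = c(16L, 16L))
      net <- build_backbone(cfg, seed = 6)
      expect_identical(count_params(cfg), as.integer(count_params(net)))
    }
  }
})

test_that("backward passes agree with finite differences", {
  set.seed(7)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  gout <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  num_grad <- function(f, v) {
    g <- array(0, dim = dim(v) %||% length(v))
    for (i in seq_along(v)) {
      e <- 1e-5
      vp <- v; vp[i] <- vp[i] + e
      vm <- v; vm[i] <- vm[i] - e
      g[i] <- (f(vp) - f(vm)) / (2 * e)
    }
    g
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  ly <- ghostseg:::new_conv(2, 3)
  bk <- ghostseg:::conv_bwd(ly, x, gout)
  expect_lt(max(abs(num_grad(function(v)
    sum(ghostseg:::conv_fwd(ly, v) * gout), x) - bk$gx)), 1e-6)
  fW <- function(v) {
    l2 <- ly; l2$W <- matrix(v, nrow(ly$W))
    sum(ghostseg:::conv_fwd(l2, x) * gout)
  }
  expect_lt(max(abs(num_grad(fW, as.numeric(ly$W)) -
                    as.numeric(bk$gW))), 1e-6)

  ld <- ghostseg:::new_depthwise(2)
  g2 <- gout[, , 1:2]
  bkd <- ghostseg:::dwu_bwd(ld, ghostseg:::dwu_fwd(ld, x)$cache, g2)
  expect_lt(max(abs(num_grad(function(v)
    sum(ghostseg:::dwu_fwd(ld, v)$out * g2), x) - bkd$gx)), 1e-6)

  lt <- ghostseg:::new_tconv(2, 3)
  gt <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  bkt <- ghostseg:::tconv_bwd(lt, x, gt)
  expect_lt(max(abs(num_grad(function(v)
    sum(ghostseg:::tconv_fwd(lt, v) * gt), x) - bkt$gx)), 1e-6)

  # linear ghost module end to end
  gcfg <- ghost_config(2, 4, ratio = 2, use_act = FALSE)
  gw <- ghost_init(gcfg)
  gg <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  ca <- ghostseg:::ghost_fwd_cached(x, gcfg, gw)
  gbk <- ghostseg:::ghost_bwd(gcfg, gw, ca, gg)
  expect_lt(max(abs(num_grad(function(v)
    sum(ghost_forward(v, gcfg, gw) * gg), x) - gbk$gx)), 1e-6)

  # full standard net: cross-entropy gradient against finite differences
  cfg <- backbone_config(depth = 2, base_width = 4, num_classes = 3,
                         block_kind = "standard", input_size = c(8L, 8L))
  net <- build_backbone(cfg, seed = 8)
  img <- matrix(runif(64), 8, 8)
  lab <- matrix(sample(0:2, 64, TRUE), 8, 8)
  p0 <- net_params(net)
  flat <- unlist(p0)
  loss_at <- function(v) {
    n2 <- net_set_params(net, utils::relist(v, p0))
    r <- ghostseg:::net_forward(n2, img)
    ghostseg:::ce_single(r$prob, lab)
  }
  r <- ghostseg:::net_forward(net, img)
  glog <- ghostseg:::ce_grad_logits(r$prob, lab)
  db <- ghostseg:::decoder_bwd(net$decoder, r$dec$caches, glog)
  eb <- ghostseg:::encoder_bwd(net$encoder, r$enc$caches, db$g_bottleneck,
                               db$g_skips)
  ga <- unlist(list(encoder = eb$grads, decoder = db$grads))
  idx <- sample(length(flat), 40)
  for (i in idx) {
    e <- 1e-5
    vp <- flat; vp[i] <- vp[i] + e
    vm <- flat; vm[i] <- vm[i] - e
    expect_lt(abs((loss_at(vp) - loss_at(vm)) / (2 * e) - ga[i]), 1e-5)
  }
})
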