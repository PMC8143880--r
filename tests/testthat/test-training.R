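# Learning-rate schedule, augmentation, trainers, checkpointing.

test_that("stepped learning-rate schedule", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 5e-4)
  expect_equal(lr_at_epoch(cfg, 199), 5e-4)
  expect_equal(lr_at_epoch(cfg, 200), 2.5e-4)
  expect_equal(lr_at_epoch(cfg, 1000), 1.25e-4)
  expect_equal(lr_at_epoch(cfg, 2500), 5e-4 * 0.5^5)
  lrs <- lr_at_epoch(cfg, 0:2999)
  expect_true(all(diff(lrs) <= 0))
  expect_identical(sum(diff(lrs) < 0), 5L)  # one drop per decay epoch
  expect_error(train_config(lr_decay_epochs = c(100, 100)), "increasing")
})

test_that("augmentation: identity ranges, geometric consistency of mask", {
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(sample(0:3, 32 * 32, TRUE, prob = c(.7, .1, .1, .1)), 32, 32)
  idr <- list(rotate = 0, scale = c(1, 1), shear = 0, intensity = 0)
  a <- augment_sample(img, mask, ranges = idr, seed = 1)
  expect_equal(a$image, img, tolerance = 1e-12)
  expect_identical(a$mask, mask)

  # full turn returns the image up to interpolation error
  w <- ghostseg:::warp_sample(img, mask, angle = 360)
  expect_equal(w$image, img, tolerance = 1e-8)

  # nearest-neighbour labels never invent new classes; image stays in [0,1]
  for (s in 1:10) {
    a <- augment_sample(img, mask, seed = s)
    expect_true(all(unique(as.vector(a$mask)) %in% unique(as.vector(mask))))
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
  expect_identical(augment_sample(img, mask, seed = 3),
                   augment_sample(img, mask, seed = 3))
})

test_that("semi-supervised training with lambda_max = 0 follows the
          supervised baseline exactly", {
  split <- tiny_split()
  cfg <- tiny_cfg("ghost")
  tc <- train_config(max_epochs = 3, batch_size = 2, lambda_max = 0,
                     use_cutmix = FALSE, seed = 31)
  cc <- build_cc_net(cfg, seed = 32)
  plain <- test_time_net(cc)  # shares E and D_S weights at initialisation
  fit_cc <- train_semisupervised(split, cc, tc)
  fit_bl <- train_supervised_baseline(split, plain, tc)
  pc <- net_params(fit_cc$net)
  pb <- net_params(fit_bl$net)
  expect_same_params(pc$encoder, pb$encoder)
  expect_same_params(pc$dec_S, pb$decoder)
  expect_equal(fit_cc$log$L_S, fit_bl$log$L_S, tolerance = 1e-12)
})

test_that("training reduces the supervised loss on the phantom", {
  split <- tiny_split(n_subjects = 4, K = 2, test_count = 1)
  cfg <- tiny_cfg("ghost")
  net <- build_backbone(cfg, seed = 33)
  tc <- train_config(max_epochs = 30, batch_size = 4, seed = 34)
  fit <- train_supervised_baseline(split, net, tc)
  expect_lt(fit$log$L_S[30], fit$log$L_S[1])
  expect_true(all(is.finite(fit$log$L_S)))
})

test_that("baseline training never touches the unlabeled pool", {
  split <- tiny_split()
  cfg <- tiny_cfg("ghost")
  tc <- train_config(max_epochs = 2, batch_size = 2, seed = 35)
  net <- build_backbone(cfg, seed = 36)
  f1 <- train_supervised_baseline(split, net, tc)
  split2 <- split
  split2$unlabeled <- list()  # removing it changes nothing
  f2 <- train_supervised_baseline(split2, net, tc)
  expect_same_params(net_params(f1$net), net_params(f2$net))
})

test_that("training is deterministic given the seed and checkpoints
          round-trip to identical evaluations", {
  split <- tiny_split()
  cfg <- tiny_cfg("ghost")
  tc <- train_config(max_epochs = 2, batch_size = 2, seed = 37)
  cc <- build_cc_net(cfg, seed = 38)
  f1 <- train_semisupervised(split, cc, tc)
  f2 <- train_semisupervised(split, cc, tc)
  expect_same_params(net_params(f1$net), net_params(f2$net))
  expect_identical(f1$log, f2$log)

  path <- tempfile(fileext = ".rds")
  save_checkpoint(f1$net, path, train_cfg = tc, epoch = 2L)
  ck <- load_checkpoint(path)
  e1 <- evaluate_model(f1$net, split$test)
  e2 <- evaluate_model(ck$net, split$test)
  expect_identical(e1$per_subject, e2$per_subject)
  unlink(path)
})

test_that("training aborts with a diagnostic on empty labeled pools", {
  split <- tiny_split()
  split$labeled <- list()
  cfg <- tiny_cfg("ghost")
  expect_error(train_supervised_baseline(split, build_backbone(cfg, seed = 1),
                                         train_config(max_epochs = 1)),
               "labeled")
  expect_error(train_semisupervised(split, build_cc_net(cfg, seed = 1),
                                    train_config(max_epochs = 1)),
               "labeled")
})
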