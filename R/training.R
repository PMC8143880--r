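# Semi-supervised training orchestration: batch composition, augmentation,
# Adam with a stepped learning-rate schedule, the epoch loop, and the
# supervised-only baseline trainer.

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with initial learning
#' rate 5e-4 halved at epochs 200/1000/1500/1800/2100, batch size 4, 3000
#' epochs, consistency-weight cap 0.4 with the ramp-up stopping at
#' `max_epochs`, and standard augmentation (rotation up to 15 degrees,
#' isotropic scale 0.9-1.1, intensity shift up to 0.1).
#'
#' @param lr_init Initial learning rate.
#' @param lr_decay_factor Multiplicative decay applied at each decay epoch.
#' @param lr_decay_epochs Strictly increasing epochs at which the rate drops.
#' @param batch_size Labeled samples per step; the consistency branch draws
#'   an equally sized batch from the unlabeled pool.
#' @param max_epochs Number of epochs (one epoch = one pass over the labeled
#'   pool).
#' @param lambda_max Cap of the consistency weight (see [lambda_schedule()]).
#' @param stop Ramp-up stop epoch; defaults to `max_epochs`.
#' @param use_cutmix Regenerate cut-and-mixed copies of the labeled and
#'   unlabeled pools each epoch.
#' @param noise_sigma,dropout_range Feature-perturbation magnitudes (see
#'   [perturb_config()]).
#' @param augment Apply random augmentation to training samples.
#' @param aug Augmentation ranges (see [augment_sample()]).
#' @param seed Master seed; every stochastic component derives its own
#'   stream from it.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_init = 5e-4, lr_decay_factor = 0.5,
                         lr_decay_epochs = c(200L, 1000L, 1500L, 1800L, 2100L),
                         batch_size = 4L, max_epochs = 3000L,
                         lambda_max = 0.4, stop = NULL, use_cutmix = TRUE,
                         noise_sigma = 0.1, dropout_range = c(0.10, 0.40),
                         augment = TRUE,
                         aug = list(rotate = 15, scale = c(0.9, 1.1),
                                    shear = 0, intensity = 0.1),
                         seed = 1L) {
  if (is.unsorted(lr_decay_epochs, strictly = TRUE)) {
    stop("lr_decay_epochs must be strictly increasing")
  }
  stopifnot(batch_size >= 1, max_epochs >= 1, lambda_max >= 0)
  structure(list(lr_init = lr_init, lr_decay_factor = lr_decay_factor,
                 lr_decay_epochs = lr_decay_epochs,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lambda_max = lambda_max,
                 stop = as.integer(stop %||% max_epochs),
                 use_cutmix = isTRUE(use_cutmix),
                 noise_sigma = noise_sigma, dropout_range = dropout_range,
                 augment = isTRUE(augment), aug = aug,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Piecewise-constant schedule: `lr_init * lr_decay_factor^k` where `k` is
#' the number of decay epochs less than or equal to `epoch`.
#'
#' @param cfg A [train_config()].
#' @param epoch Epoch index (0-based); may be a vector.
#' @return Learning rate(s).
#' @export
lr_at_epoch <- function(cfg, epoch) {
  vapply(epoch, function(e) {
    cfg$lr_init * cfg$lr_decay_factor^sum(cfg$lr_decay_epochs <= e)
  }, numeric(1))
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = par_zeros(params), v = par_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      pp <- p; mm <- m; vv <- v
      for (i in seq_along(p)) {
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        # x[i] <- list(v) keeps NULL placeholders (e.g. parameter-free
        # bilinear upsampling) instead of deleting the element
        pp[i] <- list(r$p); mm[i] <- list(r$m); vv[i] <- list(r$v)
      }
      list(p = pp, m = mm, v = vv)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# --- gradient assembly ------------------------------------------------------

# Supervised CE gradients for a labeled batch, through D_S (or the plain
# decoder) and E. Returns encoder/decoder grads plus the mean loss.
sup_batch_grads <- function(encoder, decoder, cfg, batch) {
  n <- length(batch)
  g_enc <- NULL; g_dec <- NULL
  loss <- 0
  for (s in batch) {
    ef <- encoder_fwd(encoder, cfg, s$image)
    df <- decoder_fwd(decoder, ef$bottleneck, ef$skips)
    prob <- softmax3(df$logits)
    loss <- loss + ce_single(prob, s$mask)
    glog <- ce_grad_logits(prob, s$mask) / n
    db <- decoder_bwd(decoder, df$caches, glog)
    eb <- encoder_bwd(encoder, ef$caches, db$g_bottleneck, db$g_skips)
    g_enc <- if (is.null(g_enc)) eb$grads else par_add(g_enc, eb$grads)
    g_dec <- if (is.null(g_dec)) db$grads else par_add(g_dec, db$grads)
  }
  list(g_enc = g_enc, g_dec = g_dec, loss = loss / n)
}

# Consistency gradients for an unlabeled-pool batch: MSE between the
# (stop-gradient) supervised prediction and each auxiliary prediction,
# back-propagated through D_D / D_N and the encoder only.
unsup_batch_grads <- function(net, batch, seeds) {
  n <- length(batch)
  g_enc <- NULL; g_D <- NULL; g_N <- NULL
  loss <- 0
  for (i in seq_along(batch)) {
    x <- batch[[i]]$image
    ef <- encoder_fwd(net$encoder, net$cfg, x)
    p_S <- softmax3(decoder_fwd(net$dec_S, ef$bottleneck, ef$skips)$logits)
    bD <- feature_dropout(ef$bottleneck, net$perturb$dropout_range,
                          seed = seed_for(seeds, 1L, i), return_mask = TRUE)
    mask <- attr(bD, "mask")
    attr(bD, "mask") <- NULL
    bN <- feature_noise(ef$bottleneck, net$perturb$noise_sigma,
                        seed = seed_for(seeds, 2L, i))
    dfD <- decoder_fwd(net$dec_D, bD, ef$skips)
    dfN <- decoder_fwd(net$dec_N, bN, ef$skips)
    p_D <- softmax3(dfD$logits)
    p_N <- softmax3(dfN$logits)
    loss <- loss + mse_maps(p_S, p_D) + mse_maps(p_S, p_N)

    gpD <- 2 * (p_D - p_S) / length(p_D) / n
    gpN <- 2 * (p_N - p_S) / length(p_N) / n
    dbD <- decoder_bwd(net$dec_D, dfD$caches, softmax3_bwd(p_D, gpD))
    dbN <- decoder_bwd(net$dec_N, dfN$caches, softmax3_bwd(p_N, gpN))
    # adjoint of the perturbations: dropout multiplies by its mask, noise is
    # the identity
    g_bott <- dbD$g_bottleneck * as.vector(mask) + dbN$g_bottleneck
    g_skips <- vector("list", length(ef$skips))
    for (l in seq_along(g_skips)) {
      g_skips[[l]] <- dbD$g_skips[[l]] + dbN$g_skips[[l]]
    }
    eb <- encoder_bwd(net$encoder, ef$caches, g_bott, g_skips)
    g_enc <- if (is.null(g_enc)) eb$grads else par_add(g_enc, eb$grads)
    g_D <- if (is.null(g_D)) dbD$grads else par_add(g_D, dbD$grads)
    g_N <- if (is.null(g_N)) dbN$grads else par_add(g_N, dbN$grads)
  }
  list(g_enc = g_enc, g_D = g_D, g_N = g_N, loss = loss / n)
}

# --- pools ------------------------------------------------------------------

subjects_to_samples <- function(subjects, with_masks) {
  out <- list()
  for (su in subjects) {
    for (k in seq_along(su$images)) {
      s <- list(image = su$images[[k]])
      if (with_masks) s$mask <- su$masks[[k]]
      out[[length(out) + 1]] <- s
    }
  }
  out
}

strip_masks <- function(samples) {
  lapply(samples, function(s) list(image = s$image))
}

augment_batch <- function(batch, cfg, seed_key) {
  if (!cfg$augment) return(batch)
  for (i in seq_along(batch)) {
    a <- augment_sample(batch[[i]]$image, batch[[i]]$mask, ranges = cfg$aug,
                        seed = seed_for(seed_key, i))
    batch[[i]]$image <- a$image
    if (!is.null(batch[[i]]$mask)) batch[[i]]$mask <- a$mask
  }
  batch
}

check_finite_loss <- function(L, epoch) {
  if (!is.finite(L)) {
    stop("training diverged: non-finite loss ", L, " at epoch ", epoch,
         "; lower the learning rate or perturbation magnitudes")
  }
}

# --- trainers ---------------------------------------------------------------

#' Train the cross-consistency assembly semi-supervised
#'
#' Each step draws a labeled batch from the (cut-and-mixed) labeled pool for
#' the supervised loss and an equally sized batch from the unlabeled pool
#' (unlabeled slices, their mixed copies, and the mixed labeled copies) for
#' the consistency loss; all parameters are updated jointly by Adam on
#' `L = L_S + lambda * L_U`. One epoch is one pass over the labeled pool;
#' cut-and-mixed copies are regenerated with fresh pairings every epoch.
#'
#' @param split A [make_split()] result (labeled/unlabeled/test subjects).
#' @param net A `ghostseg_ccnet` from [build_cc_net()].
#' @param cfg A [train_config()].
#' @return List with the trained `net` and a per-epoch `log` data frame
#'   (epoch, lambda, lr, L_S, L_U, L).
#' @export
train_semisupervised <- function(split, net, cfg = train_config()) {
  labeled <- subjects_to_samples(split$labeled, with_masks = TRUE)
  if (length(labeled) == 0) stop("cannot train with an empty labeled pool")
  unlabeled <- subjects_to_samples(split$unlabeled, with_masks = FALSE)
  use_unsup <- cfg$lambda_max > 0
  if (use_unsup && length(unlabeled) == 0) {
    stop("semi-supervised training needs at least one unlabeled slice")
  }
  net$perturb <- perturb_config(cfg$noise_sigma, cfg$dropout_range)
  params <- net_params(net)
  opt <- adam_init(params)
  log <- vector("list", cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    e0 <- epoch - 1L
    lr <- lr_at_epoch(cfg, e0)
    lambda <- lambda_schedule(e0, cfg$lambda_max, cfg$stop)

    if (cfg$use_cutmix) {
      lab_mix <- make_mixed_set(labeled, seed = seed_for(cfg$seed, 11L, epoch))
      lab_pool <- c(labeled, lab_mix)
      if (use_unsup) {
        unl_mix <- make_mixed_set(unlabeled,
                                  seed = seed_for(cfg$seed, 12L, epoch))
        unl_pool <- c(unlabeled, unl_mix, strip_masks(lab_mix))
      }
    } else {
      lab_pool <- labeled
      if (use_unsup) unl_pool <- unlabeled
    }

    ord <- with_seed(seed_for(cfg$seed, 13L, epoch),
                     sample.int(length(lab_pool)))
    n_steps <- ceiling(length(ord) / cfg$batch_size)
    LS_acc <- 0; LU_acc <- 0
    for (step in seq_len(n_steps)) {
      take <- ord[((step - 1) * cfg$batch_size + 1):
                  min(step * cfg$batch_size, length(ord))]
      lab_batch <- augment_batch(lab_pool[take], cfg,
                                 seed_for(cfg$seed, 14L, epoch, step))
      sg <- sup_batch_grads(net$encoder, net$dec_S, net$cfg, lab_batch)
      LS_acc <- LS_acc + sg$loss
      grads <- list(encoder = sg$g_enc, dec_S = sg$g_dec,
                    dec_D = par_zeros(params$dec_D),
                    dec_N = par_zeros(params$dec_N))

      if (use_unsup) {
        idx <- with_seed(seed_for(cfg$seed, 15L, epoch, step),
                         sample.int(length(unl_pool), cfg$batch_size,
                                    replace = TRUE))
        unl_batch <- augment_batch(strip_masks(unl_pool[idx]), cfg,
                                   seed_for(cfg$seed, 16L, epoch, step))
        ug <- unsup_batch_grads(net, unl_batch,
                                seeds = seed_for(cfg$seed, 17L, epoch, step))
        LU_acc <- LU_acc + ug$loss
        grads$encoder <- par_add(grads$encoder, ug$g_enc, scale = lambda)
        grads$dec_D <- par_add(grads$dec_D, ug$g_D, scale = lambda)
        grads$dec_N <- par_add(grads$dec_N, ug$g_N, scale = lambda)
      }

      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params
      opt <- upd$state
      net <- net_set_params(net, params)
    }
    L_S <- LS_acc / n_steps
    L_U <- if (use_unsup) LU_acc / n_steps else 0
    rep <- total_loss(L_S, L_U, lambda)
    check_finite_loss(rep$L, epoch)
    log[[epoch]] <- data.frame(epoch = epoch, lambda = lambda, lr = lr,
                               L_S = L_S, L_U = L_U, L = rep$L)
  }
  list(net = net, log = do.call(rbind, log), optimizer = opt)
}

#' Train a supervised-only baseline
#'
#' Trains a plain segmentation network from scratch on the labeled subjects
#' with standard augmentation; the unlabeled pool is never touched. Batch
#' order and augmentation draws use the same seed streams as
#' [train_semisupervised()], so with cut-and-mix disabled and
#' `lambda_max = 0` the two trainers visit identical batches.
#'
#' @param split A [make_split()] result; only `split$labeled` is read.
#' @param net A `ghostseg_net` from [build_backbone()].
#' @param cfg A [train_config()] (`lambda_max`, perturbation and cut-mix
#'   settings are ignored).
#' @return List with the trained `net` and a per-epoch `log` data frame.
#' @export
train_supervised_baseline <- function(split, net, cfg = train_config()) {
  labeled <- subjects_to_samples(split$labeled, with_masks = TRUE)
  if (length(labeled) == 0) stop("cannot train with an empty labeled pool")
  params <- net_params(net)
  opt <- adam_init(params)
  log <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    e0 <- epoch - 1L
    lr <- lr_at_epoch(cfg, e0)
    ord <- with_seed(seed_for(cfg$seed, 13L, epoch),
                     sample.int(length(labeled)))
    n_steps <- ceiling(length(ord) / cfg$batch_size)
    LS_acc <- 0
    for (step in seq_len(n_steps)) {
      take <- ord[((step - 1) * cfg$batch_size + 1):
                  min(step * cfg$batch_size, length(ord))]
      batch <- augment_batch(labeled[take], cfg,
                             seed_for(cfg$seed, 14L, epoch, step))
      sg <- sup_batch_grads(net$encoder, net$decoder, net$cfg, batch)
      LS_acc <- LS_acc + sg$loss
      grads <- list(encoder = sg$g_enc, decoder = sg$g_dec)
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params
      opt <- upd$state
      net <- net_set_params(net, params)
    }
    L_S <- LS_acc / n_steps
    check_finite_loss(L_S, epoch)
    log[[epoch]] <- data.frame(epoch = epoch, lambda = 0, lr = lr,
                               L_S = L_S, L_U = 0, L = L_S)
  }
  list(net = net, log = do.call(rbind, log), optimizer = opt)
}

# --- checkpoints ------------------------------------------------------------

#' Save a training checkpoint
#'
#' Stores the architecture config, all weights, optimizer state, epoch and
#' seeds in one file; [load_checkpoint()] restores a network that evaluates
#' bit-identically.
#'
#' @param net A `ghostseg_net` or `ghostseg_ccnet`.
#' @param path Output file path.
#' @param train_cfg,optimizer,epoch Optional training state to store.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path, train_cfg = NULL, optimizer = NULL,
                            epoch = NULL) {
  saveRDS(list(class = class(net), cfg = net$cfg,
               perturb = if (inherits(net, "ghostseg_ccnet")) net$perturb,
               params = net_params(net), train_cfg = train_cfg,
               optimizer = optimizer, epoch = epoch,
               version = as.character(utils::packageVersion("ghostseg"))),
          path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return List with the restored `net` plus any stored training state.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- if ("ghostseg_ccnet" %in% ck$class) {
    build_cc_net(ck$cfg, perturb = ck$perturb, seed = 0L)
  } else {
    build_backbone(ck$cfg, seed = 0L)
  }
  net <- net_set_params(net, ck$params)
  list(net = net, train_cfg = ck$train_cfg, optimizer = ck$optimizer,
       epoch = ck$epoch, version = ck$version)
}
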