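# Primitive trainable layers and the conv blocks assembled from them.
# Each layer is a plain list holding its weights. Convolution units carry an
# optional instance-normalisation stage (affine, per channel over space);
# when present the conv bias is dropped (the norm's beta plays that role).
# Unit forward functions return the output plus a cache for the matching
# backward function.

EMPTY3 <- array(0, dim = c(1L, 1L, 1L))

new_conv <- function(a, b, k = 3, norm = FALSE) {
  fan_in <- k * k * a
  ly <- list(type = "conv", k = k, pad = (k - 1L) %/% 2L, a = a, b = b,
             norm = norm,
             W = matrix(stats::rnorm(fan_in * b, 0, sqrt(2 / fan_in)),
                        fan_in, b),
             bias = rep(0, b))
  if (norm) {
    ly$gamma <- rep(1, b)
    ly$beta <- rep(0, b)
  }
  ly
}

new_depthwise <- function(c, k = 3, norm = FALSE) {
  fan_in <- k * k
  ly <- list(type = "dw", k = k, pad = (k - 1L) %/% 2L, c = c, norm = norm,
             W = matrix(stats::rnorm(fan_in * c, 0, sqrt(2 / fan_in)),
                        fan_in, c),
             bias = rep(0, c))
  if (norm) {
    ly$gamma <- rep(1, c)
    ly$beta <- rep(0, c)
  }
  ly
}

new_tconv <- function(a, b) {
  fan_in <- 4 * a
  list(type = "tconv", a = a, b = b,
       W = matrix(stats::rnorm(a * 4 * b, 0, sqrt(2 / fan_in)), a, 4 * b),
       bias = rep(0, b))
}

layer_params <- function(ly) {
  if (isTRUE(ly$norm)) list(W = ly$W, gamma = ly$gamma, beta = ly$beta)
  else list(W = ly$W, bias = ly$bias)
}

layer_set <- function(ly, p) {
  ly$W <- p$W
  if (isTRUE(ly$norm)) {
    ly$gamma <- p$gamma
    ly$beta <- p$beta
  } else {
    ly$bias <- p$bias
  }
  ly
}

# Plain (cache-free) convolution forward, used where no norm is involved.
conv_fwd <- function(ly, x, relu = FALSE) {
  cpp_conv2d_fwd(x, ly$W, ly$bias, ly$k, ly$pad, relu)
}
conv_bwd <- function(ly, x, gout, out = EMPTY3, relu = FALSE,
                     need_gx = TRUE) {
  cpp_conv2d_bwd(x, ly$W, ly$k, ly$pad, gout, out, relu, need_gx)
}
tconv_fwd <- function(ly, x) cpp_tconv2_fwd(x, ly$W, ly$bias)
tconv_bwd <- function(ly, x, gout) cpp_tconv2_bwd(x, ly$W, gout)

# Conv unit: conv [+ instance norm] [+ ReLU], with cache.
cu_fwd <- function(ly, x, relu = FALSE) {
  if (isTRUE(ly$norm)) {
    y <- cpp_conv2d_fwd(x, ly$W, ly$bias, ly$k, ly$pad, FALSE)
    r <- cpp_instnorm_fwd(y, ly$gamma, ly$beta, relu)
    list(out = r$out,
         cache = list(x = x, out = r$out, xhat = r$xhat, istd = r$istd))
  } else {
    out <- cpp_conv2d_fwd(x, ly$W, ly$bias, ly$k, ly$pad, relu)
    list(out = out, cache = list(x = x, out = out))
  }
}

cu_bwd <- function(ly, cache, gout, relu = FALSE, need_gx = TRUE) {
  if (isTRUE(ly$norm)) {
    rn <- cpp_instnorm_bwd(gout, cache$out, cache$xhat, cache$istd,
                           ly$gamma, relu)
    rc <- cpp_conv2d_bwd(cache$x, ly$W, ly$k, ly$pad, rn$gx, EMPTY3, FALSE,
                         need_gx)
    list(gx = rc$gx,
         grads = list(W = rc$gW, gamma = rn$ggamma, beta = rn$gbeta))
  } else {
    r <- cpp_conv2d_bwd(cache$x, ly$W, ly$k, ly$pad, gout, cache$out, relu,
                        need_gx)
    list(gx = r$gx, grads = list(W = r$gW, bias = r$gb))
  }
}

# Depthwise unit, same contract.
dwu_fwd <- function(ly, x, relu = FALSE) {
  if (isTRUE(ly$norm)) {
    y <- cpp_depthwise_fwd(x, ly$W, ly$bias, ly$k, ly$pad, FALSE)
    r <- cpp_instnorm_fwd(y, ly$gamma, ly$beta, relu)
    list(out = r$out,
         cache = list(x = x, out = r$out, xhat = r$xhat, istd = r$istd))
  } else {
    out <- cpp_depthwise_fwd(x, ly$W, ly$bias, ly$k, ly$pad, relu)
    list(out = out, cache = list(x = x, out = out))
  }
}

dwu_bwd <- function(ly, cache, gout, relu = FALSE) {
  if (isTRUE(ly$norm)) {
    rn <- cpp_instnorm_bwd(gout, cache$out, cache$xhat, cache$istd,
                           ly$gamma, relu)
    r <- cpp_depthwise_bwd(cache$x, ly$W, ly$k, ly$pad, rn$gx, EMPTY3, FALSE)
    list(gx = r$gx,
         grads = list(W = r$gW, gamma = rn$ggamma, beta = rn$gbeta))
  } else {
    r <- cpp_depthwise_bwd(cache$x, ly$W, ly$k, ly$pad, gout, cache$out,
                           relu)
    list(gx = r$gx, grads = list(W = r$gW, bias = r$gb))
  }
}

# ---------------------------------------------------------------------------
# Ghost module: a primary 3x3 convolution produces b/s "intrinsic" channels;
# the remaining channels are s-1 cheap per-channel 3x3 transforms of those,
# plus the identity copy, concatenated. s = 1 degenerates to a single
# standard convolution.

#' Ghost module configuration
#'
#' Describes one Ghost convolution block: a standard `primary_kernel`
#' convolution generating `out_channels / ratio` intrinsic feature maps,
#' followed by `ratio - 1` cheap depthwise `cheap_kernel` transforms of those
#' maps; the intrinsic maps themselves form the identity group, so the block
#' outputs `out_channels` channels at a fraction of the parameters of a
#' standard convolution.
#'
#' @param in_channels Number of input channels (`a`).
#' @param out_channels Number of output channels (`b`); must be divisible by
#'   `ratio`.
#' @param ratio Compression ratio `s` (default 4). `ratio = 1` makes the block
#'   a single standard convolution.
#' @param primary_kernel,cheap_kernel Kernel sizes (default 3).
#' @param use_bias Include bias terms (ignored when `use_norm` is set; the
#'   norm's shift takes over).
#' @param use_act Apply a ReLU after the primary and cheap stages. The
#'   identity group is the post-activation primary output, so the first
#'   `out_channels / ratio` output channels always equal the intrinsic maps.
#' @param use_norm Apply affine instance normalisation after the primary and
#'   cheap convolutions (before the activation).
#' @return A `ghost_config` list.
#' @export
ghost_config <- function(in_channels, out_channels, ratio = 4L,
                         primary_kernel = 3L, cheap_kernel = 3L,
                         use_bias = TRUE, use_act = TRUE, use_norm = FALSE) {
  stopifnot(in_channels >= 1, out_channels >= 1, ratio >= 1)
  if (out_channels %% ratio != 0) {
    stop("out_channels (", out_channels, ") must be divisible by ratio (",
         ratio, ")")
  }
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio),
                 primary_kernel = as.integer(primary_kernel),
                 cheap_kernel = as.integer(cheap_kernel),
                 use_bias = isTRUE(use_bias) && !isTRUE(use_norm),
                 use_act = isTRUE(use_act),
                 use_norm = isTRUE(use_norm)),
            class = "ghost_config")
}

#' Initialise weights for a Ghost module
#'
#' @param cfg A [ghost_config()].
#' @return A weight list with a `primary` convolution and `ratio - 1` `cheap`
#'   depthwise transforms.
#' @export
ghost_init <- function(cfg) {
  bs <- cfg$out_channels %/% cfg$ratio
  primary <- new_conv(cfg$in_channels,
                      if (cfg$ratio == 1) cfg$out_channels else bs,
                      k = cfg$primary_kernel, norm = cfg$use_norm)
  cheap <- list()
  if (cfg$ratio > 1) {
    cheap <- lapply(seq_len(cfg$ratio - 1), function(i) {
      new_depthwise(bs, k = cfg$cheap_kernel, norm = cfg$use_norm)
    })
  }
  if (!cfg$use_bias && !cfg$use_norm) {
    primary$bias[] <- 0
    cheap <- lapply(cheap, function(l) { l$bias[] <- 0; l })
  }
  list(primary = primary, cheap = cheap)
}

#' Forward pass through a Ghost module
#'
#' @param x Input feature array `(h, w, in_channels)` (a plain matrix is
#'   treated as one channel).
#' @param cfg A [ghost_config()].
#' @param weights Weights from [ghost_init()] (or trained).
#' @return Feature array `(h, w, out_channels)`. The first
#'   `out_channels / ratio` channels are the intrinsic (identity-group) maps.
#' @export
ghost_forward <- function(x, cfg, weights) {
  ghost_fwd_cached(x, cfg, weights)$out
}

ghost_fwd_cached <- function(x, cfg, weights) {
  x <- as_feature(x)
  if (dim(x)[3] != cfg$in_channels) {
    stop("input has ", dim(x)[3], " channels, config expects ",
         cfg$in_channels)
  }
  rp <- cu_fwd(weights$primary, x, relu = cfg$use_act)
  fp <- rp$out
  if (cfg$ratio == 1) {
    return(list(out = fp, p = rp$cache, fp = fp, cheap = list()))
  }
  groups <- vector("list", cfg$ratio)
  groups[[1]] <- fp
  cheap_caches <- vector("list", cfg$ratio - 1)
  for (j in seq_len(cfg$ratio - 1)) {
    rj <- dwu_fwd(weights$cheap[[j]], fp, relu = cfg$use_act)
    cheap_caches[[j]] <- rj$cache
    groups[[j + 1]] <- rj$out
  }
  d <- dim(fp)
  out <- array(unlist(groups, use.names = FALSE),
               dim = c(d[1], d[2], cfg$out_channels))
  list(out = out, p = rp$cache, fp = fp, cheap = cheap_caches)
}

ghost_bwd <- function(cfg, weights, cache, gout, need_gx = TRUE) {
  bs <- dim(cache$fp)[3]
  g_cheap <- vector("list", max(cfg$ratio - 1, 0))
  if (cfg$ratio > 1) {
    g_fp <- gout[, , seq_len(bs), drop = FALSE]  # identity group
    for (j in seq_len(cfg$ratio - 1)) {
      gg <- gout[, , j * bs + seq_len(bs), drop = FALSE]
      r <- dwu_bwd(weights$cheap[[j]], cache$cheap[[j]], gg,
                   relu = cfg$use_act)
      g_cheap[[j]] <- r$grads
      g_fp <- g_fp + r$gx
    }
  } else {
    g_fp <- gout
  }
  r <- cu_bwd(weights$primary, cache$p, g_fp, relu = cfg$use_act,
              need_gx = need_gx)
  list(gx = r$gx, grads = list(primary = r$grads, cheap = g_cheap))
}

#' Parameter count of a Ghost module
#'
#' Closed form for the weights:
#' `k_p^2 * a * (b/s) + (s - 1) * (b/s) * k_c^2`, plus bias or affine-norm
#' terms per configuration.
#'
#' @param cfg A [ghost_config()].
#' @return Integer parameter count.
#' @export
ghost_param_count <- function(cfg) {
  a <- cfg$in_channels; b <- cfg$out_channels; s <- cfg$ratio
  bs <- b %/% s
  kp <- cfg$primary_kernel; kc <- cfg$cheap_kernel
  n <- if (s == 1) kp^2 * a * b else kp^2 * a * bs + (s - 1) * bs * kc^2
  if (cfg$use_norm) n <- n + 2 * b
  else if (cfg$use_bias) n <- n + b
  as.integer(n)
}

# ---------------------------------------------------------------------------
# Conv blocks: two successive units (standard conv or ghost modules), with
# instance norm + ReLU inside each unit when configured.

new_block <- function(a, b, kind = c("standard", "ghost"), ratio = 4L,
                      norm = FALSE) {
  kind <- match.arg(kind)
  if (kind == "standard") {
    units <- list(new_conv(a, b, norm = norm), new_conv(b, b, norm = norm))
    cfgs <- NULL
  } else {
    cfgs <- list(ghost_config(a, b, ratio = ratio, use_norm = norm),
                 ghost_config(b, b, ratio = ratio, use_norm = norm))
    units <- lapply(cfgs, ghost_init)
  }
  list(kind = kind, a = a, b = b, units = units, cfgs = cfgs)
}

block_fwd <- function(block, x) {
  x <- as_feature(x)
  if (block$kind == "standard") {
    r1 <- cu_fwd(block$units[[1]], x, relu = TRUE)
    r2 <- cu_fwd(block$units[[2]], r1$out, relu = TRUE)
    list(out = r2$out, cache = list(c1 = r1$cache, c2 = r2$cache))
  } else {
    c1 <- ghost_fwd_cached(x, block$cfgs[[1]], block$units[[1]])
    c2 <- ghost_fwd_cached(c1$out, block$cfgs[[2]], block$units[[2]])
    list(out = c2$out, cache = list(c1 = c1, c2 = c2))
  }
}

block_bwd <- function(block, cache, gout, need_gx = TRUE) {
  if (block$kind == "standard") {
    r2 <- cu_bwd(block$units[[2]], cache$c2, gout, relu = TRUE)
    r1 <- cu_bwd(block$units[[1]], cache$c1, r2$gx, relu = TRUE,
                 need_gx = need_gx)
    list(gx = r1$gx, grads = list(r1$grads, r2$grads))
  } else {
    r2 <- ghost_bwd(block$cfgs[[2]], block$units[[2]], cache$c2, gout)
    r1 <- ghost_bwd(block$cfgs[[1]], block$units[[1]], cache$c1, r2$gx,
                    need_gx = need_gx)
    list(gx = r1$gx, grads = list(r1$grads, r2$grads))
  }
}

block_params <- function(block) {
  if (block$kind == "standard") {
    lapply(block$units, layer_params)
  } else {
    lapply(block$units, function(u) {
      list(primary = layer_params(u$primary),
           cheap = lapply(u$cheap, layer_params))
    })
  }
}

block_set_params <- function(block, params) {
  if (block$kind == "standard") {
    for (i in seq_along(block$units)) {
      block$units[[i]] <- layer_set(block$units[[i]], params[[i]])
    }
  } else {
    for (i in seq_along(block$units)) {
      block$units[[i]]$primary <- layer_set(block$units[[i]]$primary,
                                            params[[i]]$primary)
      for (j in seq_along(block$units[[i]]$cheap)) {
        block$units[[i]]$cheap[[j]] <-
          layer_set(block$units[[i]]$cheap[[j]], params[[i]]$cheap[[j]])
      }
    }
  }
  block
}
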