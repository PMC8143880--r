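# U-Net style encoder-decoder backbone, with standard conv or Ghost blocks.

#' Backbone architecture configuration
#'
#' A classic U-Net layout: `depth` resolution levels whose channel width
#' doubles per level from `base_width`, two convolution units per level,
#' 2x2 max pooling between encoder levels, and a mirrored decoder with skip
#' connections. `block_kind = "ghost"` replaces every interior 3x3
#' convolution with a Ghost module of ratio `ghost_ratio`; the 1x1 classifier
#' and any transposed-convolution resampling stay standard.
#'
#' @param depth Number of resolution levels (default 5).
#' @param base_width Channels at the first level; doubles per level. Must be
#'   divisible by `ghost_ratio` for ghost blocks.
#' @param bottleneck_width Channels of the deepest block. Defaults to
#'   `base_width * 2^(depth-1)` (the doubling rule); the full-scale preset
#'   overrides it as its calibration knob.
#' @param in_channels Input image channels (default 1, grayscale MR).
#' @param num_classes Output classes (default 4: background, RV, MYO, LV).
#' @param block_kind `"standard"` or `"ghost"`.
#' @param ghost_ratio Ghost compression ratio `s` (default 4).
#' @param upsample_kind `"bilinear"` (parameter-free) or `"transposed_conv"`.
#' @param norm `"instance"` (affine instance normalisation inside every conv
#'   unit; the default) or `"none"`.
#' @param input_size Expected `(height, width)` of inputs; must be divisible
#'   by `2^(depth-1)`.
#' @return A `backbone_config` object.
#' @export
backbone_config <- function(depth = 5L, base_width = 64L,
                            bottleneck_width = NULL, in_channels = 1L,
                            num_classes = 4L,
                            block_kind = c("standard", "ghost"),
                            ghost_ratio = 4L,
                            upsample_kind = c("bilinear", "transposed_conv"),
                            norm = c("instance", "none"),
                            input_size = c(160L, 160L)) {
  block_kind <- match.arg(block_kind)
  upsample_kind <- match.arg(upsample_kind)
  norm <- match.arg(norm)
  depth <- as.integer(depth); base_width <- as.integer(base_width)
  stopifnot(depth >= 2, base_width >= 1, num_classes >= 2, in_channels >= 1)
  widths <- base_width * 2L^(seq_len(depth - 1L) - 1L)
  if (is.null(bottleneck_width)) {
    bottleneck_width <- base_width * 2L^(depth - 1L)
  }
  bottleneck_width <- as.integer(bottleneck_width)
  if (block_kind == "ghost") {
    bad <- c(widths, bottleneck_width) %% ghost_ratio != 0
    if (any(bad)) {
      stop("ghost blocks need every level width divisible by ghost_ratio = ",
           ghost_ratio)
    }
  }
  structure(list(depth = depth, base_width = base_width,
                 widths = widths, bottleneck_width = bottleneck_width,
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 block_kind = block_kind,
                 ghost_ratio = as.integer(ghost_ratio),
                 upsample_kind = upsample_kind, norm = norm,
                 input_size = as.integer(input_size)),
            class = "backbone_config")
}

#' Full-scale backbone preset
#'
#' The frozen five-level configuration whose standard-convolution test-time
#' network (encoder plus one decoder) lands on 35.5 M trainable parameters:
#' widths 68/136/272/544 with a calibrated 1092-channel bottleneck and
#' parameter-free bilinear upsampling. The ghost variant shares the layout
#' with ratio 4.
#'
#' @param block_kind `"standard"` or `"ghost"`.
#' @return A [backbone_config()].
#' @export
full_scale_config <- function(block_kind = c("standard", "ghost")) {
  block_kind <- match.arg(block_kind)
  backbone_config(depth = 5L, base_width = 68L, bottleneck_width = 1092L,
                  in_channels = 1L, num_classes = 4L, block_kind = block_kind,
                  ghost_ratio = 4L, upsample_kind = "bilinear",
                  input_size = c(160L, 160L))
}

# Layer plan: shapes only, used both to build networks and to count
# parameters/FLOPs without allocating weights.
backbone_plan <- function(cfg) {
  d <- cfg$depth
  w <- cfg$widths
  enc <- vector("list", d)
  prev <- cfg$in_channels
  for (l in seq_len(d - 1)) {
    enc[[l]] <- list(a = prev, b = w[l])
    prev <- w[l]
  }
  enc[[d]] <- list(a = prev, b = cfg$bottleneck_width)
  dec <- vector("list", d - 1)
  prev <- cfg$bottleneck_width
  for (i in seq_len(d - 1)) {
    l <- d - i
    if (cfg$upsample_kind == "bilinear") {
      dec[[i]] <- list(level = l, up = NULL, block = list(a = prev + w[l],
                                                          b = w[l]))
    } else {
      dec[[i]] <- list(level = l, up = list(a = prev, b = w[l]),
                       block = list(a = 2L * w[l], b = w[l]))
    }
    prev <- w[l]
  }
  list(enc = enc, dec = dec, final = list(a = w[1], b = cfg$num_classes))
}

make_decoder <- function(cfg, plan) {
  norm <- cfg$norm == "instance"
  levels <- lapply(plan$dec, function(pl) {
    up <- if (is.null(pl$up)) NULL else new_tconv(pl$up$a, pl$up$b)
    list(level = pl$level, up = up,
         block = new_block(pl$block$a, pl$block$b, kind = cfg$block_kind,
                           ratio = cfg$ghost_ratio, norm = norm))
  })
  # the 1x1 classifier stays a plain biased convolution
  list(levels = levels, final = new_conv(plan$final$a, plan$final$b, k = 1))
}

make_encoder <- function(cfg, plan) {
  norm <- cfg$norm == "instance"
  list(blocks = lapply(plan$enc, function(pl) {
    new_block(pl$a, pl$b, kind = cfg$block_kind, ratio = cfg$ghost_ratio,
              norm = norm)
  }))
}

#' Build a segmentation network
#'
#' Constructs the encoder-decoder backbone described by `cfg` with freshly
#' initialised (He) weights. The network maps an image slice of
#' `cfg$input_size` to a per-pixel class probability map.
#'
#' @param cfg A [backbone_config()].
#' @param seed Optional integer; when given, initialisation is drawn from an
#'   isolated RNG stream.
#' @return A `ghostseg_net` object.
#' @export
build_backbone <- function(cfg, seed = NULL) {
  plan <- backbone_plan(cfg)
  build <- function() {
    structure(list(cfg = cfg, encoder = make_encoder(cfg, plan),
                   decoder = make_decoder(cfg, plan)),
              class = "ghostseg_net")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

check_input_size <- function(cfg, x) {
  d <- dim(x)
  div <- 2^(cfg$depth - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop("input of size ", d[1], "x", d[2], " is not divisible by 2^(depth-1) = ",
         div)
  }
  invisible(TRUE)
}

encoder_fwd <- function(encoder, cfg, x) {
  x <- as_feature(x)
  check_input_size(cfg, x)
  L <- length(encoder$blocks)
  skips <- vector("list", L - 1)
  caches <- vector("list", L)
  h <- x
  for (l in seq_len(L - 1)) {
    r <- block_fwd(encoder$blocks[[l]], h)
    skips[[l]] <- r$out
    p <- cpp_maxpool2_fwd(r$out)
    caches[[l]] <- list(block = r$cache, pool_idx = p$idx,
                        size = dim(r$out)[1:2])
    h <- p$out
  }
  r <- block_fwd(encoder$blocks[[L]], h)
  caches[[L]] <- list(block = r$cache)
  list(skips = skips, bottleneck = r$out, caches = caches)
}

encoder_bwd <- function(encoder, caches, g_bottleneck, g_skips) {
  L <- length(encoder$blocks)
  grads <- vector("list", L)
  r <- block_bwd(encoder$blocks[[L]], caches[[L]]$block, g_bottleneck)
  grads[[L]] <- r$grads
  gx <- r$gx
  for (l in rev(seq_len(L - 1))) {
    sz <- caches[[l]]$size
    g <- cpp_maxpool2_bwd(gx, caches[[l]]$pool_idx, sz[1], sz[2])
    if (!is.null(g_skips[[l]])) g <- g + g_skips[[l]]
    r <- block_bwd(encoder$blocks[[l]], caches[[l]]$block, g,
                   need_gx = l > 1)
    grads[[l]] <- r$grads
    gx <- r$gx
  }
  list(grads = grads, gx = gx)
}

decoder_fwd <- function(decoder, bottleneck, skips) {
  n <- length(decoder$levels)
  caches <- vector("list", n)
  h <- bottleneck
  for (i in seq_len(n)) {
    lv <- decoder$levels[[i]]
    if (is.null(lv$up)) {
      hu <- cpp_upsample2_fwd(h)
      up_cache <- list(kind = "bilinear", insize = dim(h)[1:2])
    } else {
      hu <- tconv_fwd(lv$up, h)
      up_cache <- list(kind = "tconv", x = h)
    }
    sk <- skips[[lv$level]]
    hc <- concat3(hu, sk)
    r <- block_fwd(lv$block, hc)
    caches[[i]] <- list(up = up_cache, n_up = dim(hu)[3], block = r$cache)
    h <- r$out
  }
  logits <- conv_fwd(decoder$final, h)
  caches$final_in <- h
  list(logits = logits, caches = caches)
}

decoder_bwd <- function(decoder, caches, g_logits) {
  n <- length(decoder$levels)
  rf <- conv_bwd(decoder$final, caches$final_in, g_logits)
  grads <- list(levels = vector("list", n),
                final = list(W = rf$gW, bias = rf$gb))
  g_skips <- vector("list", n)  # indexed by level later
  gh <- rf$gx
  for (i in rev(seq_len(n))) {
    lv <- decoder$levels[[i]]
    ca <- caches[[i]]
    r <- block_bwd(lv$block, ca$block, gh)
    ghc <- r$gx
    nu <- ca$n_up
    g_up <- ghc[, , seq_len(nu), drop = FALSE]
    g_skips[[lv$level]] <- ghc[, , -seq_len(nu), drop = FALSE]
    if (ca$up$kind == "bilinear") {
      gh <- cpp_upsample2_bwd(g_up, ca$up$insize[1], ca$up$insize[2])
      grads$levels[[i]] <- list(up = NULL, block = r$grads)
    } else {
      ru <- tconv_bwd(lv$up, ca$up$x, g_up)
      gh <- ru$gx
      grads$levels[[i]] <- list(up = list(W = ru$gW, bias = ru$gb),
                                block = r$grads)
    }
  }
  list(grads = grads, g_bottleneck = gh, g_skips = g_skips)
}

net_forward <- function(net, x) {
  ef <- encoder_fwd(net$encoder, net$cfg, x)
  df <- decoder_fwd(net$decoder, ef$bottleneck, ef$skips)
  prob <- softmax3(df$logits)
  list(prob = prob, logits = df$logits, enc = ef, dec = df)
}

#' Predict a class probability map for one image slice
#'
#' @param net A `ghostseg_net` or `ghostseg_ccnet` (the supervised path
#'   `D_S o E` is used).
#' @param x Image matrix in `[0, 1]` of the network's input size.
#' @return Array `(h, w, num_classes)` of per-pixel probabilities.
#' @export
predict_prob <- function(net, x) {
  if (inherits(net, "ghostseg_ccnet")) {
    ef <- encoder_fwd(net$encoder, net$cfg, x)
    softmax3(decoder_fwd(net$dec_S, ef$bottleneck, ef$skips)$logits)
  } else {
    net_forward(net, x)$prob
  }
}

#' Predict an integer label mask (argmax) for one image slice
#'
#' @inheritParams predict_prob
#' @return Integer matrix with values in `0 .. num_classes - 1`.
#' @export
predict_mask <- function(net, x) {
  p <- predict_prob(net, x)
  d <- dim(p)
  m <- matrix(0L, d[1], d[2])
  best <- p[, , 1]
  for (k in seq_len(d[3])[-1]) {
    sel <- p[, , k] > best
    m[sel] <- k - 1L
    best[sel] <- p[, , k][sel]
  }
  m
}

# --- parameter access -------------------------------------------------------

encoder_params <- function(encoder) lapply(encoder$blocks, block_params)

decoder_params <- function(decoder) {
  list(levels = lapply(decoder$levels, function(lv) {
    list(up = if (is.null(lv$up)) NULL else layer_params(lv$up),
         block = block_params(lv$block))
  }), final = layer_params(decoder$final))
}

encoder_set_params <- function(encoder, params) {
  for (i in seq_along(encoder$blocks)) {
    encoder$blocks[[i]] <- block_set_params(encoder$blocks[[i]], params[[i]])
  }
  encoder
}

decoder_set_params <- function(decoder, params) {
  for (i in seq_along(decoder$levels)) {
    if (!is.null(decoder$levels[[i]]$up)) {
      decoder$levels[[i]]$up$W <- params$levels[[i]]$up$W
      decoder$levels[[i]]$up$bias <- params$levels[[i]]$up$bias
    }
    decoder$levels[[i]]$block <-
      block_set_params(decoder$levels[[i]]$block, params$levels[[i]]$block)
  }
  decoder$final$W <- params$final$W
  decoder$final$bias <- params$final$bias
  decoder
}

#' Extract all trainable parameters of a network
#'
#' @param net A `ghostseg_net` or `ghostseg_ccnet`.
#' @return A nested list of numeric leaves (weights and biases).
#' @export
net_params <- function(net) {
  if (inherits(net, "ghostseg_ccnet")) {
    list(encoder = encoder_params(net$encoder),
         dec_S = decoder_params(net$dec_S),
         dec_D = decoder_params(net$dec_D),
         dec_N = decoder_params(net$dec_N))
  } else {
    list(encoder = encoder_params(net$encoder),
         decoder = decoder_params(net$decoder))
  }
}

#' Replace all trainable parameters of a network
#'
#' @param net A `ghostseg_net` or `ghostseg_ccnet`.
#' @param params A nested list as returned by [net_params()].
#' @return The updated network.
#' @export
net_set_params <- function(net, params) {
  if (inherits(net, "ghostseg_ccnet")) {
    net$encoder <- encoder_set_params(net$encoder, params$encoder)
    net$dec_S <- decoder_set_params(net$dec_S, params$dec_S)
    net$dec_D <- decoder_set_params(net$dec_D, params$dec_D)
    net$dec_N <- decoder_set_params(net$dec_N, params$dec_N)
  } else {
    net$encoder <- encoder_set_params(net$encoder, params$encoder)
    net$decoder <- decoder_set_params(net$decoder, params$decoder)
  }
  net
}

#' @export
print.ghostseg_net <- function(x, ...) {
  cfg <- x$cfg
  cat("<ghostseg_net> ", cfg$block_kind, " blocks, depth ", cfg$depth,
      ", widths ", paste(cfg$widths, collapse = "/"), "+",
      cfg$bottleneck_width, "\n", sep = "")
  cat("  input ", paste(cfg$input_size, collapse = "x"), ", ",
      cfg$num_classes, " classes, ", format(count_params(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}
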