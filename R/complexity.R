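# Trainable-parameter and FLOP accounting, computed analytically from the
# architecture plan (no weight allocation needed at full scale).

block_param_count <- function(a, b, kind, ratio, norm) {
  if (kind == "standard") {
    extra <- if (norm) 2 * b else b  # affine norm or bias, per unit
    (9 * a * b + extra) + (9 * b * b + extra)
  } else {
    ghost_param_count(ghost_config(a, b, ratio = ratio, use_norm = norm)) +
      ghost_param_count(ghost_config(b, b, ratio = ratio, use_norm = norm))
  }
}

plan_param_counts <- function(cfg) {
  plan <- backbone_plan(cfg)
  norm <- cfg$norm == "instance"
  enc <- sum(vapply(plan$enc, function(pl) {
    block_param_count(pl$a, pl$b, cfg$block_kind, cfg$ghost_ratio, norm)
  }, numeric(1)))
  dec <- sum(vapply(plan$dec, function(pl) {
    up <- if (is.null(pl$up)) 0 else 4 * pl$up$a * pl$up$b + pl$up$b
    up + block_param_count(pl$block$a, pl$block$b, cfg$block_kind,
                           cfg$ghost_ratio, norm)
  }, numeric(1)))
  dec <- dec + plan$final$a * plan$final$b + plan$final$b
  list(encoder = enc, decoder = dec)
}

# FLOPs for one forward pass: 1 MAC = 2 FLOPs, convolution and
# transposed-convolution layers only (bias, activations, pooling and
# bilinear resampling excluded).
block_flops <- function(a, b, kind, ratio, h, w) {
  if (kind == "standard") {
    2 * 9 * (a * b + b * b) * h * w
  } else {
    bs <- b / ratio
    g1 <- 2 * 9 * (a * bs + (ratio - 1) * bs) * h * w
    g2 <- 2 * 9 * (b * bs + (ratio - 1) * bs) * h * w
    g1 + g2
  }
}

plan_flop_counts <- function(cfg, input_shape = cfg$input_size) {
  plan <- backbone_plan(cfg)
  d <- cfg$depth
  h <- input_shape[1]; w <- input_shape[2]
  enc <- 0
  for (l in seq_len(d)) {
    hw <- c(h, w) / 2^(l - 1)
    enc <- enc + block_flops(plan$enc[[l]]$a, plan$enc[[l]]$b,
                             cfg$block_kind, cfg$ghost_ratio, hw[1], hw[2])
  }
  dec <- 0
  for (i in seq_len(d - 1)) {
    pl <- plan$dec[[i]]
    hw <- c(h, w) / 2^(pl$level - 1)
    if (!is.null(pl$up)) {
      # transposed conv runs on the coarser grid
      dec <- dec + 2 * 4 * pl$up$a * pl$up$b * (hw[1] / 2) * (hw[2] / 2)
    }
    dec <- dec + block_flops(pl$block$a, pl$block$b, cfg$block_kind,
                             cfg$ghost_ratio, hw[1], hw[2])
  }
  dec <- dec + 2 * plan$final$a * plan$final$b * h * w
  list(encoder = enc, decoder = dec)
}

#' Count trainable parameters
#'
#' For a built network the weights are enumerated exactly; for a
#' [backbone_config()] the count is computed from the layer plan in closed
#' form (the two agree, which the test suite checks).
#'
#' @param x A `ghostseg_net`, `ghostseg_ccnet` or `backbone_config`.
#' @return Integer-valued parameter count.
#' @export
count_params <- function(x) UseMethod("count_params")

#' @export
count_params.ghostseg_net <- function(x) as.integer(par_count(net_params(x)))

#' @export
count_params.ghostseg_ccnet <- function(x) {
  as.integer(par_count(net_params(x)))
}

#' @export
count_params.backbone_config <- function(x) {
  pc <- plan_param_counts(x)
  as.integer(pc$encoder + pc$decoder)
}

#' Count forward-pass FLOPs
#'
#' Convention: one multiply-accumulate = 2 FLOPs, counted over convolution,
#' depthwise and transposed-convolution layers for a single input of the
#' stated shape; normalisation/activation/pooling operations are excluded.
#'
#' @param x A `backbone_config`, `ghostseg_net` or `ghostseg_ccnet`.
#' @param input_shape `(height, width)` of the input slice; defaults to the
#'   config's `input_size`.
#' @return FLOP count (numeric; may exceed integer range).
#' @export
count_flops <- function(x, input_shape = NULL) {
  cfg <- if (inherits(x, "backbone_config")) x else x$cfg
  if (is.null(input_shape)) input_shape <- cfg$input_size
  fc <- plan_flop_counts(cfg, input_shape)
  n_dec <- if (inherits(x, "ghostseg_ccnet")) 3 else 1
  fc$encoder + n_dec * fc$decoder
}

#' Model-complexity report
#'
#' Tabulates trainable parameters and FLOPs of the cross-consistency
#' assembly at training time (shared encoder + three decoders) and test time
#' (encoder + supervised decoder), for standard-convolution and ghost
#' variants of the same layout.
#'
#' @param cfg A [backbone_config()]; defaults to the full-scale preset. The
#'   `block_kind` field is overridden to produce both rows.
#' @param input_shape Input slice shape for the FLOP counts.
#' @return A `ghostseg_complexity` data frame with raw counts, millions of
#'   parameters and billions of FLOPs.
#' @export
complexity_report <- function(cfg = full_scale_config(),
                              input_shape = NULL) {
  if (is.null(input_shape)) input_shape <- cfg$input_size
  rows <- lapply(c("standard", "ghost"), function(kind) {
    k_cfg <- cfg
    k_cfg$block_kind <- kind
    pc <- plan_param_counts(k_cfg)
    fc <- plan_flop_counts(k_cfg, input_shape)
    data.frame(block_kind = kind,
               params_train = pc$encoder + 3 * pc$decoder,
               params_test = pc$encoder + pc$decoder,
               flops_train = fc$encoder + 3 * fc$decoder,
               flops_test = fc$encoder + fc$decoder)
  })
  out <- do.call(rbind, rows)
  out$params_train_M <- out$params_train / 1e6
  out$params_test_M <- out$params_test / 1e6
  out$flops_train_G <- out$flops_train / 1e9
  out$flops_test_G <- out$flops_test / 1e9
  attr(out, "input_shape") <- input_shape
  attr(out, "flop_convention") <- "1 MAC = 2 FLOPs; conv layers only"
  class(out) <- c("ghostseg_complexity", "data.frame")
  out
}

#' @export
print.ghostseg_complexity <- function(x, ...) {
  cat("Model complexity (input ",
      paste(attr(x, "input_shape"), collapse = "x"), "; ",
      attr(x, "flop_convention"), ")\n", sep = "")
  cat(sprintf("%-22s %12s %12s %12s %12s\n", "", "train params",
              "test params", "train FLOPs", "test FLOPs"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-22s %10.1f M %10.1f M %10.1f G %10.1f G\n",
                x$block_kind[i], x$params_train_M[i], x$params_test_M[i],
                x$flops_train_G[i], x$flops_test_G[i]))
  }
  invisible(x)
}
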