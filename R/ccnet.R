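# Shared-encoder / three-decoder cross-consistency assembly.

#' Build a cross-consistency assembly
#'
#' One shared encoder `E` and three architecturally identical decoders with
#' independent weights: the supervised decoder `D_S`, the dropout decoder
#' `D_D` and the noise decoder `D_N`. The supervised path is `f_S = D_S o E`;
#' the auxiliary paths decode perturbed bottleneck features,
#' `f_D = D_D o P_D o E` and `f_N = D_N o P_N o E`.
#'
#' @param cfg A [backbone_config()].
#' @param perturb A [perturb_config()] giving the feature-perturbation
#'   magnitudes.
#' @param seed Optional integer for reproducible initialisation.
#' @return A `ghostseg_ccnet` object.
#' @export
build_cc_net <- function(cfg, perturb = perturb_config(), seed = NULL) {
  plan <- backbone_plan(cfg)
  build <- function() {
    structure(list(cfg = cfg,
                   encoder = make_encoder(cfg, plan),
                   dec_S = make_decoder(cfg, plan),
                   dec_D = make_decoder(cfg, plan),
                   dec_N = make_decoder(cfg, plan),
                   perturb = perturb),
              class = "ghostseg_ccnet")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Forward an image through all three prediction paths
#'
#' The encoder runs once; the supervised decoder sees the clean bottleneck
#' feature, the dropout decoder a spatially-dropped version and the noise
#' decoder a Gaussian-noised version. Skip connections are passed to all
#' decoders unperturbed.
#'
#' @param net A `ghostseg_ccnet`.
#' @param x Image matrix of the network's input size.
#' @param seed Integer seed driving the two perturbation draws; fixed seed
#'   gives bit-identical outputs.
#' @param perturb Logical; `FALSE` disables both feature perturbations.
#' @return List with probability maps `p_S`, `p_D`, `p_N`.
#' @export
forward_paths <- function(net, x, seed = 1L, perturb = TRUE) {
  ef <- encoder_fwd(net$encoder, net$cfg, x)
  p_S <- softmax3(decoder_fwd(net$dec_S, ef$bottleneck, ef$skips)$logits)
  if (perturb) {
    bD <- feature_dropout(ef$bottleneck, net$perturb$dropout_range,
                          seed = seed_for(seed, 1L))
    bN <- feature_noise(ef$bottleneck, net$perturb$noise_sigma,
                        seed = seed_for(seed, 2L))
  } else {
    bD <- ef$bottleneck
    bN <- ef$bottleneck
  }
  p_D <- softmax3(decoder_fwd(net$dec_D, bD, ef$skips)$logits)
  p_N <- softmax3(decoder_fwd(net$dec_N, bN, ef$skips)$logits)
  list(p_S = p_S, p_D = p_D, p_N = p_N)
}

#' Extract the test-time network (encoder plus supervised decoder)
#'
#' @param net A `ghostseg_ccnet`.
#' @return A `ghostseg_net` sharing the assembly's weights.
#' @export
test_time_net <- function(net) {
  structure(list(cfg = net$cfg, encoder = net$encoder, decoder = net$dec_S),
            class = "ghostseg_net")
}

#' @export
print.ghostseg_ccnet <- function(x, ...) {
  cfg <- x$cfg
  cat("<ghostseg_ccnet> shared encoder + 3 decoders (", cfg$block_kind,
      " blocks)\n", sep = "")
  cat("  training-time parameters: ",
      format(count_params(x), big.mark = ","), "\n", sep = "")
  cat("  test-time parameters (E + D_S): ",
      format(count_params(test_time_net(x)), big.mark = ","), "\n", sep = "")
  invisible(x)
}
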