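# Training objective: supervised cross-entropy, unsupervised cross-model
# consistency, the combined loss and the exponential ramp-up weight.

CLAMP <- 1e-7

ce_single <- function(prob, label, num_classes = dim(prob)[3]) {
  if (any(label < 0 | label > num_classes - 1)) {
    stop("label values outside 0..", num_classes - 1)
  }
  h <- dim(prob)[1]; w <- dim(prob)[2]
  idx <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h),
               as.vector(label) + 1L)
  pt <- prob[idx]
  -mean(log(pmax(pt, CLAMP)))
}

# Gradient of the per-pixel-mean CE w.r.t. the logits: (p - onehot) / (h w).
ce_grad_logits <- function(prob, label) {
  d <- dim(prob)
  g <- prob
  h <- d[1]; w <- d[2]
  idx <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h),
               as.vector(label) + 1L)
  g[idx] <- g[idx] - 1
  g / (h * w)
}

#' Supervised segmentation loss
#'
#' Mean pixel-wise multiclass cross-entropy between predicted probability
#' maps and integer label masks, averaged over the sample list. Probabilities
#' are clamped at `1e-7` before the log.
#'
#' @param preds A probability array `(h, w, C)` or a list of them.
#' @param labels An integer mask (values `0 .. C-1`) or a list of them,
#'   aligned with `preds`.
#' @return Nonnegative scalar loss.
#' @export
supervised_loss <- function(preds, labels) {
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(labels)) labels <- list(labels)
  stopifnot(length(preds) == length(labels))
  mean(mapply(ce_single, preds, labels))
}

mse_maps <- function(a, b) mean((a - b)^2)

#' Unsupervised cross-consistency loss
#'
#' For each sample, the mean-squared error between the supervised prediction
#' and each auxiliary prediction, summed over the two auxiliary paths and
#' averaged over samples:
#' `(1/N) * sum_i [ d(p_S_i, p_D_i) + d(p_S_i, p_N_i) ]` with `d` the mean
#' over pixels and classes of squared differences. The supervised maps act as
#' fixed targets: during training no gradient flows into `D_S` through this
#' loss.
#'
#' @param p_S,p_D,p_N Probability arrays or aligned lists of them.
#' @return Nonnegative scalar loss.
#' @export
consistency_loss <- function(p_S, p_D, p_N) {
  if (!is.list(p_S)) { p_S <- list(p_S); p_D <- list(p_D); p_N <- list(p_N) }
  stopifnot(length(p_S) == length(p_D), length(p_S) == length(p_N))
  for (i in seq_along(p_S)) {
    if (!identical(dim(p_S[[i]]), dim(p_D[[i]])) ||
        !identical(dim(p_S[[i]]), dim(p_N[[i]]))) {
      stop("probability maps must share the same shape")
    }
  }
  mean(mapply(function(s, d, n) mse_maps(s, d) + mse_maps(s, n),
              p_S, p_D, p_N))
}

#' Consistency ramp-up schedule for the trade-off weight
#'
#' `lambda(epoch) = min(lambda_max, lambda_max * exp(2 * epoch / stop - 1))`:
#' the weight starts at `lambda_max / e` at epoch 0, rises exponentially and
#' is capped at `lambda_max` from epoch `stop / 2` onwards.
#'
#' @param epoch Current epoch index (0-based, >= 0); may be a vector.
#' @param lambda_max Upper bound of the weight (default 0.4).
#' @param stop Epoch count after which the weight stops increasing (> 0);
#'   conventionally the maximum number of training epochs.
#' @return The weight value(s) in `[lambda_max / e, lambda_max]`.
#' @export
lambda_schedule <- function(epoch, lambda_max = 0.4, stop = 3000L) {
  if (stop <= 0) stop("schedule stop must be a positive epoch count")
  stopifnot(lambda_max >= 0, all(epoch >= 0))
  pmin(lambda_max, lambda_max * exp(2 * epoch / stop - 1))
}

#' Combine supervised and consistency losses
#'
#' @param L_S Supervised loss value.
#' @param L_U Consistency loss value.
#' @param lambda Trade-off weight.
#' @return A `loss_report` list with `L_S`, `L_U`, `lambda` and
#'   `L = L_S + lambda * L_U`.
#' @export
total_loss <- function(L_S, L_U, lambda) {
  if (!all(is.finite(c(L_S, L_U, lambda)))) {
    stop("non-finite loss input: L_S=", L_S, " L_U=", L_U, " lambda=", lambda)
  }
  structure(list(L_S = L_S, L_U = L_U, lambda = lambda,
                 L = L_S + lambda * L_U),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("L = %.6f  (L_S = %.6f, L_U = %.6f, lambda = %.4f)\n",
              x$L, x$L_S, x$L_U, x$lambda))
  invisible(x)
}
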