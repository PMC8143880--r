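# Evaluation criteria: Dice overlap and Hausdorff distance, per structure
# (RV, MYO, LV), per subject, with means over a test set.

STRUCTURES <- c(RV = 1L, MYO = 2L, LV = 3L)

as_region <- function(x) {
  if (is.logical(x)) x else x != 0
}

#' Dice overlap coefficient
#'
#' `2 |X ∩ Y| / (|X| + |Y|)` between two binary regions on the same grid.
#' Conventions: both regions empty gives 1, exactly one empty gives 0. The
#' alternative normalisation `2 |X ∩ Y| / |X ∪ Y|` (which exceeds 1 on
#' partial overlap) is available for audit via `variant = "printed"`.
#'
#' @param X,Y Binary (logical or 0/1) arrays of identical shape, any
#'   dimensionality.
#' @param variant `"standard"` (default) or `"printed"`.
#' @return Overlap value in `[0, 1]` (standard variant).
#' @export
dice <- function(X, Y, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  X <- as_region(X); Y <- as_region(Y)
  if (!identical(dim(X) %||% length(X), dim(Y) %||% length(Y))) {
    stop("regions must be on the same grid")
  }
  nx <- sum(X); ny <- sum(Y)
  if (nx == 0 && ny == 0) return(1)
  if (nx == 0 || ny == 0) return(0)
  inter <- sum(X & Y)
  if (variant == "standard") 2 * inter / (nx + ny)
  else 2 * inter / sum(X | Y)
}

region_coords <- function(X, spacing) {
  idx <- which(X)
  if (length(idx) == 0) return(NULL)
  co <- arrayInd(idx, dim(X) %||% c(length(X), 1L))
  sweep(co, 2, spacing[seq_len(ncol(co))], `*`)
}

directed_hd <- function(A, B, chunk = 2048L) {
  nb2 <- rowSums(B^2)
  worst <- 0
  for (start in seq(1, nrow(A), by = chunk)) {
    ai <- A[start:min(start + chunk - 1, nrow(A)), , drop = FALSE]
    d2 <- outer(rowSums(ai^2), nb2, `+`) - 2 * tcrossprod(ai, B)
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(max(worst, 0))
}

#' Hausdorff distance between two regions
#'
#' The larger of the two directed maximum point-to-set Euclidean distances,
#' computed over the full foreground point sets with per-axis physical
#' spacing (mm): `max(max_{a in X} E(a, Y), max_{b in Y} E(b, X))`.
#'
#' @param X,Y Binary arrays of identical shape (2D or 3D).
#' @param spacing Physical size of one cell per axis (mm); recycled/truncated
#'   to the array dimensionality. Default 1 per axis.
#' @return Distance in mm; `NA` with a warning if either region is empty.
#' @export
hausdorff <- function(X, Y, spacing = rep(1, 3)) {
  X <- as_region(X); Y <- as_region(Y)
  if (!identical(dim(X) %||% length(X), dim(Y) %||% length(Y))) {
    stop("regions must be on the same grid")
  }
  stopifnot(all(spacing > 0))
  A <- region_coords(X, spacing)
  B <- region_coords(Y, spacing)
  if (is.null(A) || is.null(B)) {
    warning("Hausdorff distance undefined for an empty region")
    return(NA_real_)
  }
  max(directed_hd(A, B), directed_hd(B, A))
}

#' Evaluate a segmentation network on test subjects
#'
#' Predicts each slice by per-pixel argmax over the probability map, stacks
#' the slices per subject, and computes per-structure (RV, MYO, LV) Dice (in
#' percent) and Hausdorff distance (in mm, using the subject's voxel
#' spacing) on the per-subject 3D stacks, plus means over subjects.
#'
#' @param net A trained `ghostseg_net` or `ghostseg_ccnet` (uses `D_S o E`).
#' @param subjects List of labeled subjects (see [generate_subject()] /
#'   [load_acdc_subject()]) whose slices match the network input size.
#' @param predict_fn Optional replacement predictor `function(image)` for a
#'   single slice returning an integer mask (used e.g. for oracle checks).
#' @return A `ghostseg_eval` list with `per_subject` and `summary` data
#'   frames.
#' @export
evaluate_model <- function(net, subjects, predict_fn = NULL) {
  if (is.null(predict_fn)) predict_fn <- function(img) predict_mask(net, img)
  rows <- list()
  for (su in subjects) {
    if (length(su$images) == 0) {
      warning("subject ", su$id, " has no slices; skipped")
      next
    }
    d <- dim(su$images[[1]])
    nsl <- length(su$images)
    pred <- array(0L, dim = c(d, nsl))
    gt <- array(0L, dim = c(d, nsl))
    for (k in seq_len(nsl)) {
      pred[, , k] <- predict_fn(su$images[[k]])
      gt[, , k] <- su$masks[[k]]
    }
    spacing <- su$spacing %||% c(1, 1, 1)
    for (st in names(STRUCTURES)) {
      lab <- STRUCTURES[[st]]
      P <- pred == lab
      G <- gt == lab
      hd <- if (sum(P) == 0 || sum(G) == 0) {
        if (sum(G) > 0 || sum(P) > 0) {
          warning("empty region for ", st, " in subject ", su$id,
                  "; Hausdorff reported as NA")
        }
        NA_real_
      } else {
        hausdorff(P, G, spacing)
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = su$id, structure = st,
        dice = 100 * dice(P, G), hausdorff = hd)
    }
  }
  per_subject <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(names(STRUCTURES), function(st) {
    d <- per_subject[per_subject$structure == st, ]
    data.frame(structure = st, dice = mean(d$dice),
               hausdorff = mean(d$hausdorff, na.rm = TRUE))
  }))
  summ <- rbind(summ, data.frame(structure = "Mean",
                                 dice = mean(summ$dice),
                                 hausdorff = mean(summ$hausdorff)))
  structure(list(per_subject = per_subject, summary = summ),
            class = "ghostseg_eval")
}

#' @export
print.ghostseg_eval <- function(x, ...) {
  cat("Segmentation evaluation over", length(unique(x$per_subject$subject)),
      "subjects\n")
  s <- x$summary
  s$dice <- sprintf("%.1f", s$dice)
  s$hausdorff <- sprintf("%.2f", s$hausdorff)
  names(s) <- c("structure", "DICE (%)", "Hausdorff (mm)")
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to CSV
#'
#' One row per subject per structure plus summary rows.
#'
#' @param report A `ghostseg_eval` from [evaluate_model()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  per <- report$per_subject
  summ <- cbind(subject = "mean", report$summary)
  utils::write.csv(rbind(per, summ), path, row.names = FALSE)
  invisible(path)
}
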