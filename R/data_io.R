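# ACDC-style NIfTI input, slice preprocessing and subject-level splits.

#' Load one ACDC-style subject directory
#'
#' Expects NIfTI volumes named `<id>_frameXX.nii[.gz]` with optional
#' ground-truth companions `<id>_frameXX_gt.nii[.gz]`. Volumes are split
#' into 2D slices; voxel spacing is carried through from the header. A
#' subject with no ground-truth volumes is loaded as unlabeled
#' (`masks = NULL`). The first two frames are tagged ED and ES.
#'
#' @param path Subject directory.
#' @return A subject list: `id`, `images`, `masks` (or NULL), `spacing`
#'   (row, col, slice in mm), `phases`.
#' @export
load_acdc_subject <- function(path) {
  files <- sort(list.files(path, pattern = "_frame[0-9]+\\.nii(\\.gz)?$",
                           full.names = TRUE))
  files <- files[!grepl("_gt\\.nii", files)]
  if (length(files) == 0) {
    stop("no NIfTI frame volumes found under ", path)
  }
  id <- sub("_frame[0-9]+\\.nii(\\.gz)?$", "", basename(files[1]))
  images <- list()
  masks <- list()
  phases <- character(0)
  spacing <- c(1, 1, 1)
  any_gt <- FALSE
  phase_names <- c("ED", "ES")
  for (fi in seq_along(files)) {
    f <- files[fi]
    vol <- RNifti::readNifti(f)
    pd <- attr(vol, "pixdim") %||% RNifti::pixdim(vol)
    if (!is.null(pd) && length(pd) >= 3) spacing <- pd[1:3]
    gt_f <- sub("\\.nii(\\.gz)?$", "_gt.nii\\1", f)
    gt <- NULL
    if (file.exists(gt_f)) {
      gt <- RNifti::readNifti(gt_f)
      any_gt <- TRUE
      if (!all(as.vector(gt) %in% 0:3)) {
        stop("ground truth in ", gt_f, " has labels outside {0,1,2,3}")
      }
    }
    vol <- as.array(vol)
    if (length(dim(vol)) == 2) vol <- array(vol, dim = c(dim(vol), 1L))
    tag <- if (fi <= 2) phase_names[fi] else paste0("frame", fi)
    for (k in seq_len(dim(vol)[3])) {
      images[[length(images) + 1]] <- vol[, , k]
      phases <- c(phases, tag)
      if (!is.null(gt)) {
        m <- as.array(gt)
        if (length(dim(m)) == 2) m <- array(m, dim = c(dim(m), 1L))
        mm <- m[, , k]
        storage.mode(mm) <- "integer"
        masks[[length(masks) + 1]] <- mm
      }
    }
  }
  list(id = id, images = images,
       masks = if (any_gt) masks else NULL,
       spacing = as.numeric(spacing), phases = phases)
}

#' Load every subject under a dataset root
#'
#' @param root Directory whose subdirectories are subjects.
#' @return List of subjects.
#' @export
load_acdc_dataset <- function(root) {
  dirs <- list.dirs(root, recursive = FALSE)
  if (length(dirs) == 0) stop("no subject directories under ", root)
  lapply(dirs, load_acdc_subject)
}

#' Preprocess one slice for the network
#'
#' Resizes to the target size (bilinear for intensities, nearest neighbour
#' for the mask) and min-max rescales intensities to `[0, 1]` per slice; a
#' constant slice maps to all zeros. Physical in-plane spacing should be
#' rescaled by `original_size / target_size` by the caller when Hausdorff
#' distances in mm are needed after resizing.
#'
#' @param img 2D image matrix.
#' @param mask Optional 2D integer mask.
#' @param size Target `(height, width)`, default `c(160, 160)`.
#' @return List with `image` (and `mask` if given).
#' @export
preprocess_slice <- function(img, mask = NULL, size = c(160L, 160L)) {
  if (length(dim(img)) != 2) stop("preprocess_slice expects a 2D slice")
  out <- cpp_resize(img, size[1], size[2], nearest = FALSE)
  rng <- range(out)
  out <- if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1]) else out * 0
  res <- list(image = out)
  if (!is.null(mask)) {
    m <- cpp_resize(mask, size[1], size[2], nearest = TRUE)
    storage.mode(m) <- "integer"
    res$mask <- m
  }
  res
}

#' Preprocess all slices of a subject
#'
#' Applies [preprocess_slice()] to every slice and rescales the in-plane
#' spacing by `original / target` so physical distances stay correct.
#'
#' @param subject A subject list.
#' @param size Target slice size.
#' @return The preprocessed subject.
#' @export
preprocess_subject <- function(subject, size = c(160L, 160L)) {
  orig <- dim(subject$images[[1]])
  for (k in seq_along(subject$images)) {
    r <- preprocess_slice(subject$images[[k]],
                          if (!is.null(subject$masks)) subject$masks[[k]],
                          size = size)
    subject$images[[k]] <- r$image
    if (!is.null(subject$masks)) subject$masks[[k]] <- r$mask
  }
  subject$spacing[1:2] <- subject$spacing[1:2] * orig / size
  subject
}

#' Partition subjects into labeled / unlabeled / test pools
#'
#' Test subjects are drawn first, then `K` labeled subjects from the
#' remainder; the rest form the unlabeled pool. Subject-level partitioning
#' guarantees no test slice ever enters a training pool. Deterministic for a
#' given seed.
#'
#' @param subjects List of subjects.
#' @param K Number of labeled subjects (>= 1).
#' @param test_count Number of held-out test subjects.
#' @param seed Integer seed.
#' @return A `data_split` list with `labeled`, `unlabeled`, `test` subject
#'   lists and slice counts `n` (labeled) and `m` (unlabeled).
#' @export
make_split <- function(subjects, K, test_count, seed = 1L) {
  if (K < 1) stop("K = 0 labeled subjects cannot train a model")
  if (K + test_count > length(subjects)) {
    stop("K + test_count exceeds the number of subjects")
  }
  ids <- with_seed(seed, {
    test_idx <- sample.int(length(subjects), test_count)
    rest <- setdiff(seq_along(subjects), test_idx)
    lab_idx <- rest[sample.int(length(rest), K)]
    list(test = test_idx, labeled = lab_idx,
         unlabeled = setdiff(rest, lab_idx))
  })
  labeled <- subjects[ids$labeled]
  unlabeled <- subjects[ids$unlabeled]
  test <- subjects[ids$test]
  structure(list(labeled = labeled, unlabeled = unlabeled, test = test,
                 n = sum(vapply(labeled, function(s) length(s$images), 0L)),
                 m = sum(vapply(unlabeled, function(s) length(s$images), 0L)),
                 seed = as.integer(seed)),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("<data_split> ", length(x$labeled), " labeled subjects (n = ", x$n,
      " slices), ", length(x$unlabeled), " unlabeled (m = ", x$m,
      " slices), ", length(x$test), " test\n", sep = "")
  invisible(x)
}

#' Write a split manifest as JSON
#'
#' Records the subject ids of each pool and the seed, enough to reproduce
#' the split exactly.
#'
#' @param split A `data_split`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(
    list(seed = split$seed,
         labeled = vapply(split$labeled, `[[`, "", "id"),
         unlabeled = vapply(split$unlabeled, `[[`, "", "id"),
         test = vapply(split$test, `[[`, "", "id")),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
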