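# NIfTI round trips, preprocessing and subject-level splits.

test_that("phantom datasets round-trip through the NIfTI layout", {
  dir <- tempfile("phantom")
  subs <- generate_dataset(3, tiny_phantom(), seed = 80)
  write_phantom_dataset(subs, dir)
  back <- load_acdc_dataset(dir)
  expect_length(back, 3)
  ids <- vapply(back, `[[`, "", "id")
  expect_setequal(ids, vapply(subs, `[[`, "", "id"))
  for (su in subs) {
    lb <- back[[which(ids == su$id)]]
    expect_length(lb$images, length(su$images))
    for (k in seq_along(su$images)) {
      expect_equal(lb$images[[k]], su$images[[k]], tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(as.vector(lb$masks[[k]]), as.vector(su$masks[[k]]))
    }
    expect_equal(lb$spacing, su$spacing)
  }
  # writing without ground truth loads as an unlabeled subject
  dir2 <- tempfile("phantom_u")
  write_phantom_dataset(subs, dir2, with_gt = FALSE)
  back2 <- load_acdc_subject(list.dirs(dir2, recursive = FALSE)[1])
  expect_null(back2$masks)
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("labeled volumes with two phases yield 2 * depth slices", {
  dir <- tempfile("twophase")
  su <- generate_subject(tiny_phantom(), seed = 81, id = "sub01")
  sdir <- file.path(dir, "sub01")
  dir.create(sdir, recursive = TRUE)
  d <- dim(su$images[[1]])
  vol <- array(unlist(su$images), c(d, length(su$images)))
  gt <- array(unlist(su$masks), c(d, length(su$masks)))
  for (frame in c("frame01", "frame04")) {
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(1, 1, 1)),
                       file.path(sdir, paste0("sub01_", frame, ".nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(gt, pixdim = c(1, 1, 1)),
                       file.path(sdir, paste0("sub01_", frame, "_gt.nii.gz")))
  }
  lb <- load_acdc_subject(sdir)
  expect_length(lb$images, 2 * length(su$images))
  expect_identical(unique(lb$phases), c("ED", "ES"))
  expect_true(all(unlist(lb$masks) %in% 0:3))
  unlink(dir, recursive = TRUE)
})

test_that("preprocessing resizes, rescales to [0,1], and is idempotent", {
  img <- matrix(runif(48 * 40, min = 2, max = 9), 48, 40)
  mask <- matrix(sample(0:3, 48 * 40, TRUE), 48, 40)
  r <- preprocess_slice(img, mask, size = c(160L, 160L))
  expect_equal(dim(r$image), c(160, 160))
  expect_equal(dim(r$mask), c(160, 160))
  expect_equal(range(r$image), c(0, 1))
  expect_true(all(r$mask %in% unique(as.vector(mask))))

  # idempotence at the target size
  r2 <- preprocess_slice(r$image, r$mask, size = c(160L, 160L))
  expect_equal(r2$image, r$image, tolerance = 1e-12)
  expect_identical(r2$mask, r$mask)

  # a constant slice maps to zeros
  expect_true(all(preprocess_slice(matrix(5, 8, 8), size = c(16L, 16L))$image
                  == 0))
  expect_error(preprocess_slice(array(0, c(4, 4, 2))), "2D")

  # subject-level preprocessing rescales the in-plane spacing
  su <- generate_subject(tiny_phantom(), seed = 82)
  sp <- preprocess_subject(su, size = c(16L, 16L))
  expect_equal(sp$spacing[1:2], su$spacing[1:2] * 32 / 16)
  expect_equal(dim(sp$images[[1]]), c(16, 16))
})

test_that("splits are disjoint, exhaustive, sized as requested and seeded", {
  subs <- generate_dataset(12, tiny_phantom(), seed = 83)
  sp <- make_split(subs, K = 2, test_count = 3, seed = 84)
  expect_length(sp$labeled, 2)
  expect_length(sp$unlabeled, 7)
  expect_length(sp$test, 3)
  ids <- function(x) vapply(x, `[[`, "", "id")
  all_ids <- c(ids(sp$labeled), ids(sp$unlabeled), ids(sp$test))
  expect_setequal(all_ids, ids(subs))
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_identical(sp$n, 4L)  # 2 subjects x 2 slices
  expect_identical(make_split(subs, 2, 3, seed = 84)$labeled |> ids(),
                   ids(sp$labeled))
  expect_false(identical(ids(make_split(subs, 2, 3, seed = 85)$labeled),
                         ids(sp$labeled)))
  expect_error(make_split(subs, K = 0, test_count = 2), "K = 0")
  expect_error(make_split(subs, K = 10, test_count = 3), "exceeds")

  manifest <- tempfile(fileext = ".json")
  write_split_manifest(sp, manifest)
  j <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_setequal(j$test, ids(sp$test))
  unlink(manifest)
})
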