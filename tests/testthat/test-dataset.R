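make_patch_dirs <- function(root, n_per_class = 3, size = 24) {
  set.seed(123)
  for (k in 0:3) {
    d <- file.path(root, c("0_ears", "1_ear", "2_ears", "3_ears")[k + 1])
    dir.create(d, recursive = TRUE)
    for (i in seq_len(n_per_class)) {
      save_image(toy_patch(k, size), file.path(d, sprintf("p%02d.png", i)))
    }
  }
  root
}

test_that("labeled patches load from the class-per-directory layout", {
  root <- make_patch_dirs(withr::local_tempdir())
  ps <- load_labeled_patches(root, patch_size = c(24L, 24L))
  expect_s3_class(ps, "patch_set")
  expect_length(ps, 12L)
  expect_equal(tabulate(ps$labels + 1L, 4L), rep(3L, 4))
  expect_true(all(vapply(ps$patches, function(p) all(dim(p) == c(24, 24, 3)),
                         logical(1))))

  # unknown class directory is rejected
  dir.create(file.path(root, "5_ears"))
  expect_error(load_labeled_patches(root), "5_ears")
  unlink(file.path(root, "5_ears"), recursive = TRUE)

  # a stray non-image file is skipped with a warning, count unaffected
  writeLines("junk", file.path(root, "1_ear", "notes.txt"))
  expect_warning(ps2 <- load_labeled_patches(root, patch_size = c(24L, 24L)),
                 "skipping")
  expect_length(ps2, 12L)

  expect_error(load_labeled_patches(withr::local_tempdir()), "empty")
})

test_that("augmentation is identity under the neutral config and deterministic", {
  p <- toy_patch(1, 40)
  neutral <- augmentation_config(crop_fraction = 1, allow_hflip = FALSE,
                                 allow_vflip = FALSE, rotation_degrees = 0,
                                 brightness_range = c(1, 1))
  set.seed(5)
  expect_equal(unclass(augment_patch(p, neutral)), unclass(p),
               ignore_attr = TRUE)

  cfg <- augmentation_config()
  set.seed(11); a1 <- augment_patch(p, cfg)
  set.seed(11); a2 <- augment_patch(p, cfg)
  expect_identical(unclass(a1), unclass(a2))
  expect_equal(dim(a1), dim(p))

  # brightness 1.3 on a constant 100 patch gives a constant 130
  bright <- augmentation_config(crop_fraction = 1, allow_hflip = FALSE,
                                allow_vflip = FALSE, rotation_degrees = 0,
                                brightness_range = c(1.3, 1.3))
  set.seed(1)
  out <- augment_patch(const_image(20, 20, c(100, 100, 100)), bright)
  expect_equal(unique(as.vector(unclass(out))), 130)
  # and clipping holds at the top of the range
  set.seed(1)
  out2 <- augment_patch(const_image(20, 20, c(250, 250, 250)), bright)
  expect_equal(unique(as.vector(unclass(out2))), 255)
})

test_that("balancing grows classes exactly and splits sources disjointly", {
  set.seed(9)
  patches <- list(); labels <- integer(0); ids <- character(0)
  for (k in 0:3) {
    for (s in 1:2) {
      patches[[length(patches) + 1L]] <- toy_patch(k, 24)
      labels <- c(labels, k)
      ids <- c(ids, sprintf("src_%d_%d", k, s))
    }
  }
  ps <- patch_set(patches, labels, ids)
  ds <- balance_and_split(ps, per_class = 8L, test_per_class = 2L,
                          augmentation_config(seed = 4))
  expect_equal(ds$per_class_counts$train, rep(6L, 4))
  expect_equal(ds$per_class_counts$test, rep(2L, 4))
  expect_length(intersect(ds$train$source_id, ds$test$source_id), 0L)
  # labels and dimensions survive augmentation
  expect_true(all(ds$train$labels %in% 0:3))
  expect_true(all(vapply(ds$train$patches,
                         function(p) all(dim(p) == c(24, 24, 3)), logical(1))))

  # byte-identical rebuild under the same seed
  ds2 <- balance_and_split(ps, per_class = 8L, test_per_class = 2L,
                           augmentation_config(seed = 4))
  expect_identical(ds$train$patches, ds2$train$patches)
  expect_identical(ds$test$patches, ds2$test$patches)
  expect_identical(ds$train$source_id, ds2$train$source_id)

  # per_class equal to the source count with augmentation disabled
  # reproduces the sources exactly
  neutral <- augmentation_config(crop_fraction = 1, allow_hflip = FALSE,
                                 allow_vflip = FALSE, rotation_degrees = 0,
                                 brightness_range = c(1, 1), seed = 2)
  ds3 <- balance_and_split(ps, per_class = 2L, test_per_class = 1L, neutral)
  expect_equal(length(ds3$train) + length(ds3$test), length(ps))
  expect_setequal(c(ds3$train$source_id, ds3$test$source_id), ids)

  # a class with no sources fails loudly
  ps0 <- patch_set(patches[labels != 2], labels[labels != 2],
                   ids[labels != 2])
  expect_error(balance_and_split(ps0, 8L, 2L), "class 2")
})

test_that("patch sets round-trip through the directory layout", {
  ps <- toy_patch_set(2, size = 24, seed = 3)
  dir <- withr::local_tempdir()
  write_patch_set(ps, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- load_labeled_patches(dir, patch_size = c(24L, 24L))
  expect_length(back, length(ps))
  expect_equal(tabulate(back$labels + 1L, 4L), tabulate(ps$labels + 1L, 4L))
})
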