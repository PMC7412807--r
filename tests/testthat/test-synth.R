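test_that("scene truth conserves ear counts across configurations", {
  set.seed(808)
  for (seed in 1:4) {
    cfg <- scene_config(size = c(300, 300), n_ears = sample(0:8, 1),
                        adhesion = runif(1, 0, 0.5), clutter = 10,
                        seed = seed)
    sc <- generate_scene(cfg)
    expect_equal(sum(sc$truth$blobs$multiplicity), sc$truth$total_ears)
    expect_equal(sc$truth$total_ears, cfg$n_ears)
    # blob ids in the map match the truth table
    ids <- setdiff(unique(as.vector(sc$truth$blob_map)), 0L)
    expect_setequal(ids, sc$truth$blobs$blob)
  }
})

test_that("an ear-free scene contains no yellow-palette pixels", {
  sc <- generate_scene(scene_config(size = c(150, 150), n_ears = 0,
                                    clutter = 12, seed = 2))
  expect_equal(sc$truth$total_ears, 0L)
  expect_equal(sum(sc$truth$blob_map), 0L)
  # no pixel comes close to the ear palette colour in Lab
  px <- matrix(rgb_to_lab(sc$image), ncol = 3)
  ear_lab <- matrix(rgb_to_lab(const_image(1, 1, default_palettes()$ear$mean)),
                    ncol = 3)
  d <- sqrt(rowSums(sweep(px, 2, ear_lab)^2))
  expect_gt(min(d), 20)
})

test_that("full adhesion with pair size 2 gives three fused pairs from six ears", {
  sc <- generate_scene(scene_config(size = c(300, 300), n_ears = 6,
                                    adhesion = 1, fuse_sizes = 2L, seed = 4))
  expect_equal(nrow(sc$truth$blobs), 3L)
  expect_true(all(sc$truth$blobs$multiplicity == 2L))
  # each fused pair is one connected component in the truth map
  for (b in sc$truth$blobs$blob) {
    m <- (sc$truth$blob_map == b) * 1L
    expect_equal(max(oracle_components(m, 8)), 1L)
  }
})

test_that("scenes are bit-reproducible for a fixed seed", {
  cfg <- scene_config(size = c(200, 200), n_ears = 6, adhesion = 0.5,
                      clutter = 10, seed = 77)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(unclass(s1$image), unclass(s2$image))
  expect_identical(s1$truth$blob_map, s2$truth$blob_map)
  expect_identical(s1$truth$blobs, s2$truth$blobs)
})

test_that("patch datasets are balanced, labeled by construction, reproducible", {
  cfg <- scene_config(seed = 10)
  ps <- generate_patch_dataset(5, cfg, keep_truth = TRUE)
  expect_length(ps, 20L)
  expect_equal(tabulate(ps$labels + 1L, 4L), rep(5L, 4))
  expect_true(all(vapply(ps$patches,
                         function(p) all(dim(p) == c(100, 100, 3)),
                         logical(1))))
  # class-3 patches hold one connected blob of multiplicity 3 in the truth
  masks <- attr(ps, "truth_masks")
  for (i in which(ps$labels == 3L)) {
    expect_equal(max(oracle_components(masks[[i]] * 1L, 8)), 1L)
  }
  # class-0 patches carry no truth mask
  expect_true(all(vapply(which(ps$labels == 0L),
                         function(i) is.null(masks[[i]]), logical(1))))

  ps2 <- generate_patch_dataset(5, cfg)
  expect_identical(ps$patches, ps2$patches)
})

test_that("segmentation recovers the generator's ear mask in the easy regime", {
  sc <- generate_scene(scene_config(size = c(300, 300), n_ears = 8,
                                    adhesion = 0.25, clutter = 15, seed = 21))
  seg <- segment_image(enhance(sc$image), seg_config(seed = 13))
  tm <- sc$truth$blob_map > 0
  iou <- sum(tm & seg$mask == 1) / sum(tm | seg$mask == 1)
  expect_gte(iou, 0.7)
})

test_that("shrinking the ear/leaf contrast degrades segmentation quality", {
  # emulate the early grain-filling stage: ears still greenish
  easy <- scene_config(size = c(300, 300), n_ears = 8, clutter = 15, seed = 33)
  hard <- easy
  hard$palettes$ear$mean <- c(110, 150, 80)  # green-yellow, close to leaf
  iou_of <- function(cfg) {
    sc <- generate_scene(cfg)
    seg <- segment_image(enhance(sc$image), seg_config(seed = 13))
    tm <- sc$truth$blob_map > 0
    sum(tm & seg$mask == 1) / sum(tm | seg$mask == 1)
  }
  expect_lt(iou_of(hard), iou_of(easy))
})

test_that("scene windows scale with the ear count at fixed density", {
  cfg <- scene_config()
  s5 <- scene_size_for(5, cfg)
  s40 <- scene_size_for(40, cfg)
  expect_lt(s5, s40)
  # ear-pixel fraction stays near the target for an unclamped size
  mean_area <- pi / 4 * mean(cfg$ear_major) * mean(cfg$ear_minor)
  expect_equal(20 * mean_area / scene_size_for(20, cfg)^2, 0.05,
               tolerance = 0.01)
  # clamped at both ends
  expect_equal(scene_size_for(1, cfg), 250L)
  expect_equal(scene_size_for(1000, cfg), 700L)
})

test_that("scene writing produces decodable images and a truth table", {
  dir <- withr::local_tempdir()
  truth <- write_scenes(2, scene_config(size = c(150, 150), clutter = 8,
                                        seed = 3), ears = c(2L, 4L), dir)
  expect_equal(nrow(truth), 2L)
  expect_true(all(file.exists(file.path(dir, truth$image_id))))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  img <- load_image(file.path(dir, truth$image_id[1]))
  expect_equal(dim(img), c(150L, 150L, 3L))
  expect_true(all(truth$n_ears >= 2 & truth$n_ears <= 4))
})
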