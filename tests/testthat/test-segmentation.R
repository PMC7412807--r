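test_that("k-means recovers well-separated constant colours exactly", {
  img <- tri_color_image(30, 30)
  q <- kmeans_quantize(img, seg_config(k = 3, seed = 7))
  expect_equal(sort(unique(as.vector(q$labels))), 0:2)
  expect_lt(q$inertia, 1e-6)
  # the three centres are the three block colours (compare in Lab)
  lab <- rgb_to_lab(img)
  want <- unique(matrix(lab, ncol = 3))
  got <- q$centers[order(q$centers[, 3]), ]
  want <- want[order(want[, 3]), ]
  expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("k-means assignment matches the nearest-centre oracle and the log is monotone", {
  set.seed(31)
  img <- rgb_image(array(runif(4 * 5 * 3, 0, 255), c(4, 5, 3)))
  q <- kmeans_quantize(img, seg_config(k = 2, seed = 3))
  x <- matrix(rgb_to_lab(img), ncol = 3)
  expect_equal(as.vector(q$labels) + 1L, oracle_nearest_center(x, q$centers))
  expect_true(all(diff(q$log$inertia) <= 1e-9))
  # inertia equals the recomputed sum of squared distances
  d <- rowSums((x - q$centers[as.vector(q$labels) + 1L, ])^2)
  expect_equal(q$inertia, sum(d), tolerance = 1e-10)
  expect_error(seg_config(k = 1), "k must be")
})

test_that("k-means is no worse than stats::kmeans on the same data", {
  set.seed(11)
  img <- rgb_image(array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3)))
  q <- kmeans_quantize(img, seg_config(k = 3, seed = 5))
  x <- matrix(rgb_to_lab(img), ncol = 3)
  ref <- suppressWarnings(
    stats::kmeans(x, centers = 3, nstart = 10, iter.max = 100,
                  algorithm = "Lloyd"))
  expect_lt(q$inertia, ref$tot.withinss * 1.05)
})

test_that("ear-cluster selection picks the yellowest centre with tie rules", {
  img <- tri_color_image(24, 24)
  q <- kmeans_quantize(img, seg_config(k = 3, seed = 2))
  ear <- select_ear_cluster(q)
  # oracle: convert palette colours, the ear centre must be the max-b* one
  expect_equal(q$centers[ear + 1L, 3], max(q$centers[, 3]))
  # the selected cluster's mean RGB is the yellow block
  sel_rgb <- as.vector(lab_to_rgb(array(q$centers[ear + 1L, ], c(1, 1, 3))))
  expect_equal(round(sel_rgb), c(220, 200, 90), tolerance = 0.02)

  # identical centres: tie broken to the lower index
  q2 <- structure(list(labels = matrix(0L, 2, 2),
                       centers = rbind(c(100, 128, 150), c(100, 128, 150)),
                       inertia = 0, k = 2L), class = "quantized_image")
  expect_equal(select_ear_cluster(q2), 0L)
  # b* tie with different L: brighter wins
  q3 <- structure(list(labels = matrix(0L, 2, 2),
                       centers = rbind(c(80, 128, 150), c(180, 128, 150)),
                       inertia = 0, k = 2L), class = "quantized_image")
  expect_equal(select_ear_cluster(q3), 1L)
})

test_that("binarize maps the ear cluster to 1 and everything else to 0", {
  q <- structure(list(labels = matrix(c(0L, 2L, 1L, 0L), 2, 2),
                      centers = diag(3), inertia = 0, k = 3L),
                 class = "quantized_image")
  expect_equal(binarize(q, 0L), matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(binarize(q, 1L), matrix(c(0L, 0L, 1L, 0L), 2, 2))
  expect_error(binarize(q, 3L), "index")
  all_ear <- structure(list(labels = matrix(1L, 3, 3), centers = diag(3),
                            inertia = 0, k = 3L), class = "quantized_image")
  expect_equal(binarize(all_ear, 1L), matrix(1L, 3, 3))
  expect_equal(binarize(all_ear, 0L), matrix(0L, 3, 3))
})

test_that("morphological cleanup matches the Minkowski set-shift oracle", {
  # a 2x2 speck dies under a 6x6 opening; a 1-px hole closes
  speck <- matrix(0L, 20, 20); speck[5:6, 5:6] <- 1L
  expect_equal(sum(morph_clean(speck)), 0)
  blk <- matrix(0L, 40, 40); blk[6:35, 6:35] <- 1L; blk[20, 20] <- 0L
  expect_equal(morph_clean(blk)[20, 20], 1L)

  set.seed(99)
  for (i in 1:3) {
    m <- matrix(rbinom(40 * 40, 1, 0.45), 40, 40)
    opened <- oracle_dilate(oracle_erode(m, 6, 6), 6, 6)
    closed <- oracle_erode(oracle_dilate(opened, 3, 3), 3, 3)
    expect_equal(morph_clean(m, seg_config()), closed)
    # anti-extensivity of opening / extensivity of closing
    expect_true(all(opened <= m))
    expect_true(all(closed >= opened))
    # idempotence of both composites
    cfg1 <- seg_config(close_kernel = c(1L, 1L))
    expect_equal(morph_clean(morph_clean(m, cfg1), cfg1),
                 morph_clean(m, cfg1))
  }
})

test_that("region extraction agrees with the flood-fill oracle", {
  # five disjoint 10x10 squares
  m <- matrix(0L, 60, 60)
  at <- list(c(1, 1), c(1, 31), c(25, 13), c(47, 3), c(45, 45))
  for (p in at) m[p[1]:(p[1] + 9), p[2]:(p[2] + 9)] <- 1L
  reg <- extract_regions(m, seg_config(min_area = 50))
  expect_equal(nrow(reg), 5L)
  expect_true(all(reg$area == 100L))
  expect_true(all(reg$height == 10L & reg$width == 10L))
  expect_equal(reg$perimeter, rep(36, 5))
  # ordering by (row_min, col_min)
  expect_true(!is.unsorted(reg$row_min))

  expect_equal(nrow(extract_regions(matrix(0L, 10, 10))), 0L)

  # diagonal touch: one region under 8-connectivity, two under 4
  dm <- matrix(0L, 12, 12)
  dm[2:4, 2:4] <- 1L; dm[5:7, 5:7] <- 1L
  expect_equal(nrow(extract_regions(dm, seg_config(min_area = 0))), 1L)
  expect_equal(max(oracle_components(dm, 8)), 1L)
  expect_equal(max(oracle_components(dm, 4)), 2L)

  # randomized comparison: counts, areas, bounding boxes
  set.seed(7)
  for (i in 1:3) {
    m <- matrix(rbinom(50 * 50, 1, 0.35), 50, 50)
    reg <- extract_regions(m, seg_config(min_area = 0))
    lab <- oracle_components(m, 8)
    expect_equal(nrow(reg), max(lab))
    o_area <- sort(as.vector(table(lab[lab > 0])))
    expect_equal(sort(reg$area), as.integer(o_area))
    expect_equal(sum(reg$area), sum(m))
    for (l in seq_len(max(lab))) {
      px <- which(lab == l, arr.ind = TRUE)
      hit <- reg[reg$row_min == min(px[, 1]) - 1L &
                 reg$col_min == min(px[, 2]) - 1L &
                 reg$area == nrow(px), ]
      expect_equal(nrow(hit), 1L)
      expect_equal(hit$height, max(px[, 1]) - min(px[, 1]) + 1L)
      expect_equal(hit$width, max(px[, 2]) - min(px[, 2]) + 1L)
    }
  }

  # min_area filter: sum of kept areas <= foreground count, equal at 0
  m <- matrix(rbinom(40 * 40, 1, 0.4), 40, 40)
  expect_lte(sum(extract_regions(m, seg_config(min_area = 5))$area), sum(m))
  expect_equal(sum(extract_regions(m, seg_config(min_area = 0))$area), sum(m))
})

test_that("pad_border centres the content and fills with the given colour", {
  img <- rgb_image(array(runif(5 * 5 * 3, 0, 255), c(5, 5, 3)))
  expect_identical(unclass(pad_border(img, 0)), unclass(img))
  out <- pad_border(img, 10, c(1, 2, 3))
  expect_equal(dim(out)[1:2], c(25L, 25L))
  expect_equal(unclass(out)[11:15, 11:15, ], unclass(img),
               ignore_attr = TRUE)
  expect_equal(out[1, 1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(out[25, 25, ], c(1, 2, 3), ignore_attr = TRUE)
})

test_that("crop_patches expands, clips, and resizes to the patch size", {
  img <- rgb_image(array(runif(120 * 120 * 3, 0, 255), c(120, 120, 3)))
  # exact 100x100 bbox with zero margin: pixel-identical crop
  reg <- tibble::tibble(region_id = 1L, row_min = 10L, col_min = 5L,
                        height = 100L, width = 100L, centroid_row = 60,
                        centroid_col = 55, area = 100L, perimeter = 0)
  p <- crop_patches(img, reg, seg_config(bbox_margin = 0L))
  expect_equal(unclass(p[[1]]), unclass(img)[11:110, 6:105, ],
               ignore_attr = TRUE)

  # 50x80 bbox comes out exactly 100x100
  reg2 <- tibble::tibble(region_id = 1L, row_min = 20L, col_min = 20L,
                         height = 50L, width = 80L, centroid_row = 0,
                         centroid_col = 0, area = 1L, perimeter = 0)
  p2 <- crop_patches(img, reg2, seg_config())
  expect_equal(dim(p2[[1]])[1:2], c(100L, 100L))

  # flush with the corner: clipped expansion, no out-of-bounds
  reg3 <- tibble::tibble(region_id = 1L, row_min = 0L, col_min = 0L,
                         height = 30L, width = 30L, centroid_row = 0,
                         centroid_col = 0, area = 1L, perimeter = 0)
  expect_no_error(crop_patches(img, reg3, seg_config(bbox_margin = 4L)))

  expect_equal(crop_patches(img, empty <- extract_regions(matrix(0L, 5, 5))),
               list())
})

test_that("segment_image recovers isolated synthetic ears and is deterministic", {
  sc <- generate_scene(scene_config(size = c(300, 300), n_ears = 8,
                                    adhesion = 0, clutter = 15, seed = 3))
  expect_equal(sc$truth$total_ears, 8L)
  enh <- enhance(sc$image)
  cfg <- seg_config(seed = 11)
  seg <- segment_image(enh, cfg)
  expect_equal(nrow(seg$regions), 8L)
  expect_equal(length(seg$patches), 8L)
  # patch coordinates live in the padded frame
  expect_true(all(seg$regions$row_min + seg$regions$height <=
                  300 + 2 * cfg$border_pad))

  seg2 <- segment_image(enh, cfg)
  expect_identical(seg$regions, seg2$regions)
  expect_identical(seg$mask, seg2$mask)
  expect_identical(lapply(seg$patches, unclass), lapply(seg2$patches, unclass))

  # a scene with no ears yields no regions
  green <- const_image(120, 120, c(60, 140, 60))
  expect_equal(nrow(segment_image(green, seg_config(seed = 1))$regions), 0L)
})
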