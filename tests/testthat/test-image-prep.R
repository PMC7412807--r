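test_that("PNG round trip is lossless and bad files are rejected", {
  img <- rgb_image(array(c(10, 200, 30, 250, 0, 128, 40, 90, 60, 5, 255, 77),
                         c(2, 2, 3)))
  p <- withr::local_tempfile(fileext = ".png")
  save_image(img, p)
  back <- load_image(p)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE)

  jp <- withr::local_tempfile(fileext = ".jpg")
  EBImage::writeImage(earcount:::as_ebimage(tri_color_image(20, 24)), jp,
                      type = "jpeg", quality = 95)
  jimg <- load_image(jp)
  expect_equal(dim(jimg), c(20L, 24L, 3L))

  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("not an image", txt)
  expect_error(load_image(txt), "decode|read")
  expect_error(load_image("no/such/file.png"), "no/such/file.png")
})

test_that("center_crop takes the centred window with floor offsets", {
  # 4x4 image with distinct values: the 2x2 centre is rows/cols 1-2 (0-based)
  vals <- array(1:48, c(4, 4, 3)) * 5
  img <- rgb_image(vals %% 256)
  out <- center_crop(img, 2, 2)
  expect_equal(unclass(out), unclass(img)[2:3, 2:3, ], ignore_attr = TRUE)

  expect_equal(unclass(center_crop(img, 4, 4)), unclass(img),
               ignore_attr = TRUE)
  expect_error(center_crop(img, 5, 2), "larger")

  # idempotence: cropping twice with the same size changes nothing
  big <- rgb_image(array(runif(40 * 36 * 3, 0, 255), c(40, 36, 3)))
  once <- center_crop(big, 21, 17)
  expect_identical(unclass(center_crop(once, 21, 17)), unclass(once))

  # full-frame geometry: a large frame reduces to the centred window
  frame <- rgb_image(array(0, c(400, 300, 3)))
  expect_equal(dim(center_crop(frame, 140, 140))[1:2], c(140L, 140L))
})

test_that("resize is bilinear, exact on identity and constants", {
  img <- rgb_image(array(runif(140 * 140 * 3, 0, 255), c(140, 140, 3)))
  out <- resize_image(img, 70, 70)
  expect_equal(dim(out)[1:2], c(70L, 70L))

  expect_identical(unclass(resize_image(img, 140, 140)), unclass(img))

  const <- const_image(31, 17, c(80, 120, 160))
  r <- resize_image(const, 13, 29)
  expect_lt(max(abs(sweep(unclass(r), 3, c(80, 120, 160)))), 1e-6)

  expect_error(resize_image(img, 0, 10), ">= 1")
})

test_that("enhancement preserves dimensions, range, and flat images", {
  # tile sizes comparable to real frames (the clip limit floors out on
  # degenerate few-pixel tiles, as in any standard CLAHE)
  for (v in c(100, 128, 180)) {
    const <- const_image(160, 160, c(v, v, v))
    out <- enhance(const)
    expect_equal(dim(out), dim(const))
    # flat histogram: CLAHE maps a constant to (almost) itself
    expect_lt(max(abs(unclass(out) - v)), 1)
    expect_lt(max(out) - min(out), 1e-6)
  }
  img <- tri_color_image(64, 64)
  out <- enhance(img)
  expect_equal(dim(out), dim(img))
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
})

test_that("CLAHE increases the spread of low-contrast texture", {
  # grey texture confined to L roughly in [40, 60]
  set.seed(3)
  g <- matrix(runif(240 * 240, 95, 145), 240, 240)
  img <- rgb_image(array(rep(as.vector(g), 3), c(240, 240, 3)))
  before <- sd(rgb_to_lab(img)[, , 1])
  out <- enhance(img, median_kernel = 1)
  after <- sd(rgb_to_lab(out)[, , 1])
  expect_gt(after, before * 1.5)
})

test_that("median filter matches the sorted-neighbourhood oracle", {
  # impulse removal
  imp <- array(0, c(7, 7, 3)); imp[4, 4, ] <- 255
  out <- median_denoise(rgb_image(imp), 3)
  expect_equal(max(out), 0)

  img <- rgb_image(array(runif(5 * 5 * 3, 0, 255), c(5, 5, 3)))
  expect_identical(unclass(median_denoise(img, 1)), unclass(img))
  expect_equal(unclass(median_denoise(img, 3)), oracle_median(img, 3),
               ignore_attr = TRUE)
  big <- rgb_image(array(sample(0:255, 9 * 8 * 3, TRUE), c(9, 8, 3)))
  expect_equal(unclass(median_denoise(big, 5)), oracle_median(big, 5),
               ignore_attr = TRUE)
  expect_error(median_denoise(img, 4), "odd")

  # idempotent on piecewise-constant regions larger than the kernel
  pc <- array(0, c(20, 20, 3)); pc[1:10, , ] <- 200
  once <- median_denoise(rgb_image(pc), 3)
  expect_equal(unclass(median_denoise(once, 3)), unclass(once),
               ignore_attr = TRUE)
})

test_that("Lab round trip reproduces RGB within quantization tolerance", {
  set.seed(42)
  img <- rgb_image(array(sample(0:255, 30 * 30 * 3, TRUE), c(30, 30, 3)))
  back <- lab_to_rgb(rgb_to_lab(img))
  expect_lt(max(abs(unclass(back) - unclass(img))), 2)
  # yellow has the largest b* among the canopy palette colours
  b_of <- function(rgb) rgb_to_lab(const_image(1, 1, rgb))[1, 1, 3]
  expect_gt(b_of(c(220, 200, 90)), b_of(c(60, 140, 60)))
  expect_gt(b_of(c(220, 200, 90)), b_of(c(120, 95, 65)))
})
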