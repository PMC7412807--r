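#' Preprocessing configuration
#'
#' Bundles the geometric and enhancement parameters applied before
#' segmentation. The defaults mirror a hand-held phone frame workflow: a
#' 1400 x 1400 centre crop from the full frame, downscaling to 700 x 700,
#' CLAHE on the CIELAB L channel with clip limit 2 on an 8 x 8 tile grid,
#' and a 3 x 3 median filter. `crop`/`scale` may be `NULL` to skip those
#' steps (synthetic scenes are generated at working resolution already).
#'
#' @param crop integer length-2 `c(h, w)` centre-crop window, or `NULL`.
#' @param scale integer length-2 `c(h, w)` output size, or `NULL`.
#' @param clahe_clip positive clip limit for CLAHE.
#' @param clahe_tiles integer length-2 tile grid `c(ny, nx)`.
#' @param median_kernel odd integer median-filter window size.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(crop = c(1400L, 1400L), scale = c(700L, 700L),
                              clahe_clip = 2, clahe_tiles = c(8L, 8L),
                              median_kernel = 3L) {
  if (!is.null(crop)) stopifnot(length(crop) == 2L, all(crop >= 1))
  if (!is.null(scale)) stopifnot(length(scale) == 2L, all(scale >= 1))
  stopifnot(clahe_clip > 0, length(clahe_tiles) == 2L, all(clahe_tiles >= 1))
  if (median_kernel < 1 || median_kernel %% 2 == 0) {
    stop("median_kernel must be an odd integer >= 1", call. = FALSE)
  }
  structure(list(crop = crop, scale = scale, clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 median_kernel = as.integer(median_kernel)),
            class = "preprocess_config")
}

#' Centre crop
#'
#' Extracts a `crop_h x crop_w` window whose top-left corner is at
#' `(floor((H - crop_h) / 2), floor((W - crop_w) / 2))` (0-based).
#'
#' @param img an [rgb_image()].
#' @param crop_h,crop_w window size in pixels; must not exceed the image.
#' @return the cropped [rgb_image()].
#' @export
center_crop <- function(img, crop_h, crop_w) {
  img <- as_rgb_image(img)
  H <- img_height(img); W <- img_width(img)
  if (crop_h > H || crop_w > W) {
    stop(sprintf("crop %dx%d larger than image %dx%d", crop_h, crop_w, H, W),
         call. = FALSE)
  }
  r0 <- (H - crop_h) %/% 2L
  c0 <- (W - crop_w) %/% 2L
  rgb_image(unclass(img)[(r0 + 1L):(r0 + crop_h),
                         (c0 + 1L):(c0 + crop_w), , drop = FALSE])
}

#' Bilinear resize
#'
#' @param img an [rgb_image()].
#' @param out_h,out_w target size in pixels (>= 1).
#' @return the resized [rgb_image()].
#' @export
resize_image <- function(img, out_h, out_w) {
  img <- as_rgb_image(img)
  if (out_h < 1 || out_w < 1) stop("target size must be >= 1", call. = FALSE)
  if (out_h == img_height(img) && out_w == img_width(img)) return(img)
  # EBImage works in (x, y) = (width, height) order
  out <- EBImage::resize(as_ebimage(img), w = out_w, h = out_h,
                         filter = "bilinear")
  from_ebimage(out)
}

#' sRGB to CIELAB (8-bit convention)
#'
#' D65 standard illuminant; channels scaled to the 8-bit pipeline
#' convention: `L* * 255 / 100`, `a* + 128`, `b* + 128`, so every channel
#' nominally spans `[0, 255]`.
#'
#' @param img an [rgb_image()].
#' @return an `H x W x 3` array of L, a, b channels (doubles).
#' @export
rgb_to_lab <- function(img) {
  img <- as_rgb_image(img)
  d <- dim(img)
  m <- matrix(unclass(img), ncol = 3L) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  lab[, 1] <- lab[, 1] * 255 / 100
  lab[, 2] <- lab[, 2] + 128
  lab[, 3] <- lab[, 3] + 128
  array(lab, d)
}

#' CIELAB (8-bit convention) back to sRGB
#'
#' Inverse of [rgb_to_lab()]; output clamped to `[0, 255]`.
#'
#' @param lab an `H x W x 3` Lab array in the 8-bit convention.
#' @return an [rgb_image()].
#' @export
lab_to_rgb <- function(lab) {
  d <- dim(lab)
  m <- matrix(lab, ncol = 3L)
  m[, 1] <- m[, 1] * 100 / 255
  m[, 2] <- m[, 2] - 128
  m[, 3] <- m[, 3] - 128
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  rgb_image(array(pmin(pmax(rgb, 0), 1) * 255, d))
}

#' Contrast enhancement: CLAHE on L, then median denoising
#'
#' Converts to CIELAB (D65), applies contrast-limited adaptive histogram
#' equalization to the L channel only (per-tile histograms clipped at
#' `clahe_clip` times the uniform level, excess redistributed, bilinear
#' interpolation between tile mappings), converts back to RGB, and median
#' filters each channel. This brightens the yellowed ears relative to the
#' green stem/leaf background ahead of colour clustering.
#'
#' @inheritParams center_crop
#' @param clahe_clip positive clip limit (default 2).
#' @param clahe_tiles integer length-2 tile grid (default 8 x 8).
#' @param median_kernel odd median window (default 3); 1 disables smoothing.
#' @return the enhanced [rgb_image()], same dimensions.
#' @export
enhance <- function(img, clahe_clip = 2, clahe_tiles = c(8L, 8L),
                    median_kernel = 3L) {
  img <- as_rgb_image(img)
  stopifnot(clahe_clip > 0)
  lab <- rgb_to_lab(img)
  lab[, , 1] <- cpp_clahe(lab[, , 1], as.integer(clahe_tiles[2]),
                          as.integer(clahe_tiles[1]), clahe_clip)
  out <- lab_to_rgb(lab)
  if (median_kernel > 1) out <- median_denoise(out, median_kernel)
  out
}

#' Median filter
#'
#' Per-channel median over `kernel x kernel` neighbourhoods with
#' edge-replicated borders.
#'
#' @inheritParams center_crop
#' @param kernel odd integer window size (`1` is the identity).
#' @return the filtered [rgb_image()].
#' @export
median_denoise <- function(img, kernel = 3L) {
  img <- as_rgb_image(img)
  if (kernel < 1 || kernel %% 2 == 0) {
    stop("median kernel must be an odd integer >= 1", call. = FALSE)
  }
  if (kernel == 1L) return(img)
  d <- dim(img)
  out <- cpp_median_filter(unclass(img), d[1], d[2], d[3], as.integer(kernel))
  rgb_image(out)
}

#' Full preprocessing stage
#'
#' Optional centre crop, optional bilinear downscale, then [enhance()].
#'
#' @inheritParams center_crop
#' @param cfg a [preprocess_config()].
#' @return the preprocessed [rgb_image()].
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  img <- as_rgb_image(img)
  stopifnot(inherits(cfg, "preprocess_config"))
  if (!is.null(cfg$crop)) img <- center_crop(img, cfg$crop[1], cfg$crop[2])
  if (!is.null(cfg$scale)) img <- resize_image(img, cfg$scale[1], cfg$scale[2])
  enhance(img, cfg$clahe_clip, cfg$clahe_tiles, cfg$median_kernel)
}
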