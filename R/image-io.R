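#' RGB images as H x W x 3 arrays
#'
#' The unit every pipeline stage passes along is a numeric array with
#' dimensions height x width x 3, channel order RGB, values in `[0, 255]`.
#' `rgb_image()` validates and tags such an array; most functions also accept
#' a plain array and validate internally.
#'
#' @param x numeric array, `H x W x 3` (or `H x W`, expanded to three equal
#'   channels), values in `[0, 255]`.
#' @return an object of class `rgb_image` (an array).
#' @examples
#' img <- rgb_image(array(128, c(4, 4, 3)))
#' dim(img)
#' @export
rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("an rgb_image must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(x)[1] < 1L || dim(x)[2] < 1L) {
    stop("image dimensions must be >= 1", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  structure(x, class = c("rgb_image", "array"))
}

as_rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) x else rgb_image(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, values %.0f..%.0f>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' @export
plot.rgb_image <- function(x, ...) {
  plot(grDevices::as.raster(unclass(x) / 255), ...)
}

# keep the class through subsetting-free arithmetic done by callers
strip_class <- function(x) {
  class(x) <- "array"
  x
}

img_height <- function(img) dim(img)[1]
img_width <- function(img) dim(img)[2]

# EBImage stores images transposed (x = columns first) with values in [0, 1].
as_ebimage <- function(img) {
  EBImage::Image(aperm(unclass(img), c(2L, 1L, 3L)) / 255,
                 colormode = "Color")
}

from_ebimage <- function(im) {
  d <- EBImage::imageData(im)
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), c(dim(d), 3L))
  if (dim(d)[3] > 3L) d <- d[, , 1:3, drop = FALSE]  # drop alpha
  rgb_image(pmin(pmax(aperm(d, c(2L, 1L, 3L)), 0), 1) * 255)
}

#' Load a PNG or JPEG image
#'
#' Decodes the file and returns an [rgb_image()] in RGB channel order,
#' regardless of the on-disk layout (grayscale is expanded, alpha dropped).
#'
#' @param path path to a PNG or JPEG file.
#' @return an [rgb_image()].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read image: ", path, call. = FALSE)
  }
  im <- tryCatch(EBImage::readImage(path),
                 error = function(e) {
                   stop("cannot decode image file: ", path, call. = FALSE)
                 })
  from_ebimage(im)
}

#' Write an image as PNG
#'
#' PNG only: the tests and all intermediate artifacts use a lossless format
#' so round trips are exact.
#'
#' @param img an [rgb_image()] (or plain `H x W x 3` array).
#' @param path output path; should end in `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- as_rgb_image(img)
  EBImage::writeImage(as_ebimage(round(unclass(img))), path, type = "png")
  invisible(path)
}
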