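#' Segmentation configuration
#'
#' Parameters for colour quantization and blob extraction. Defaults follow
#' the working-resolution pipeline: 3 colour clusters (soil, leaf/stem, ear
#' -- two clusters would force the colour-transition zone into one of the
#' ear/background groups), a 6 x 6 morphological opening to remove specks
#' and burrs, a 3 x 3 closing to fill holes, a 50 px minimum blob area at
#' 700 x 700, a 10 px protective border so ears touching the frame edge stay
#' separable, a 4 px bounding-box margin, and 100 x 100 output patches.
#'
#' @param k number of colour clusters (>= 2).
#' @param seed RNG seed for the k-means++ initialization.
#' @param max_iter maximum Lloyd iterations.
#' @param tol convergence threshold on centre movement (Lab units).
#' @param open_kernel,close_kernel integer length-2 structuring-element sizes.
#' @param min_area minimum blob area in pixels.
#' @param min_yellow_margin minimum b* separation (8-bit Lab units) between
#'   the selected ear cluster and the least-yellow cluster for the scene to
#'   be considered to contain ears at all; below it [segment_image()]
#'   returns no regions (guards scenes with no yellow structures, where the
#'   "yellowest" cluster is arbitrary).
#' @param border_pad protective border width in pixels.
#' @param bbox_margin bounding-box expansion in pixels before cropping.
#' @param patch_size integer length-2 output patch size.
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(k = 3L, seed = 1L, max_iter = 100L, tol = 1e-4,
                       open_kernel = c(6L, 6L), close_kernel = c(3L, 3L),
                       min_area = 50L, min_yellow_margin = 8,
                       border_pad = 10L, bbox_margin = 4L,
                       patch_size = c(100L, 100L)) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  stopifnot(max_iter >= 1, tol >= 0, length(open_kernel) == 2L,
            length(close_kernel) == 2L, all(open_kernel >= 1),
            all(close_kernel >= 1), min_area >= 0, border_pad >= 0,
            bbox_margin >= 0, length(patch_size) == 2L, all(patch_size >= 1))
  structure(list(k = as.integer(k), seed = seed,
                 max_iter = as.integer(max_iter), tol = tol,
                 open_kernel = as.integer(open_kernel),
                 close_kernel = as.integer(close_kernel),
                 min_area = as.integer(min_area),
                 min_yellow_margin = min_yellow_margin,
                 border_pad = as.integer(border_pad),
                 bbox_margin = as.integer(bbox_margin),
                 patch_size = as.integer(patch_size)),
            class = "seg_config")
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

sq_dist_to_centers <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

#' K-means colour quantization
#'
#' Runs Lloyd's algorithm with k-means++ initialization on the per-pixel
#' CIELAB 3-vectors of the (enhanced) image. Terminates when the maximum
#' centre movement drops below `tol` or after `max_iter` iterations; the
#' returned labelling is guaranteed consistent with the final centres
#' (one closing nearest-centre assignment pass).
#'
#' @param img an [rgb_image()], normally the output of [enhance()].
#' @param cfg a [seg_config()]; `k`, `seed`, `max_iter`, `tol` are used.
#' @return an object of class `quantized_image`: list with `labels`
#'   (`H x W` integer matrix, values `0..k-1`), `centers` (`k x 3` Lab
#'   matrix, 8-bit convention), `inertia` (sum of squared distances), and
#'   `log` (tibble of per-iteration inertia and centre shift).
#' @export
kmeans_quantize <- function(img, cfg = seg_config()) {
  img <- as_rgb_image(img)
  k <- cfg$k
  lab <- rgb_to_lab(img)
  H <- dim(lab)[1]; W <- dim(lab)[2]
  x <- matrix(lab, ncol = 3L)
  res <- with_seed(cfg$seed, {
    centers <- kmeanspp_init(x, k)
    log_iter <- integer(0); log_inertia <- double(0); log_shift <- double(0)
    for (it in seq_len(cfg$max_iter)) {
      d2 <- sq_dist_to_centers(x, centers)
      assign <- max.col(-d2, ties.method = "first")
      inertia <- sum(d2[cbind(seq_along(assign), assign)])
      counts <- tabulate(assign, nbins = k)
      newc <- centers  # empty clusters keep their previous centre
      u <- sort(unique(assign))
      sums <- matrix(0, k, ncol(x))
      sums[u, ] <- rowsum(x, assign)
      nz <- counts > 0
      newc[nz, ] <- sums[nz, , drop = FALSE] / counts[nz]
      shift <- sqrt(max(rowSums((newc - centers)^2)))
      log_iter <- c(log_iter, it)
      log_inertia <- c(log_inertia, inertia)
      log_shift <- c(log_shift, shift)
      centers <- newc
      if (shift < cfg$tol) break
    }
    # closing pass: make labels/inertia consistent with the final centres
    d2 <- sq_dist_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_along(assign), assign)])
    list(centers = centers, assign = assign, inertia = inertia,
         log = tibble::tibble(iter = log_iter, inertia = log_inertia,
                              center_shift = log_shift))
  })
  structure(list(labels = matrix(res$assign - 1L, H, W),
                 centers = res$centers, inertia = res$inertia,
                 log = res$log, k = k),
            class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image %d x %d, k = %d, inertia = %.1f, %d iterations>\n",
              nrow(x$labels), ncol(x$labels), x$k, x$inertia, nrow(x$log)))
  invisible(x)
}

#' Pick the ear cluster
#'
#' At grain filling the ears are the yellowest structures in the scene, so
#' the ear cluster is the centre with the largest CIELAB b* (yellowness);
#' ties break towards larger L (brighter), then the lower index.
#'
#' @param q a `quantized_image` from [kmeans_quantize()].
#' @return the 0-based index of the ear cluster.
#' @export
select_ear_cluster <- function(q) {
  stopifnot(inherits(q, "quantized_image"), nrow(q$centers) >= 2L)
  b <- q$centers[, 3]
  L <- q$centers[, 1]
  best <- which(b == max(b))
  if (length(best) > 1L) best <- best[L[best] == max(L[best])]
  as.integer(best[1L] - 1L)
}

#' Binarize the quantized image to an ear mask
#'
#' 1 where the pixel belongs to the ear cluster, 0 elsewhere (soil and
#' leaf/stem clusters are merged into background for morphology).
#'
#' @param q a `quantized_image`.
#' @param ear_idx 0-based cluster index, e.g. from [select_ear_cluster()].
#' @return an integer `H x W` matrix with values 0/1.
#' @export
binarize <- function(q, ear_idx) {
  stopifnot(inherits(q, "quantized_image"))
  if (ear_idx < 0 || ear_idx >= q$k) {
    stop("ear_idx must be a 0-based cluster index < k", call. = FALSE)
  }
  m <- matrix(0L, nrow(q$labels), ncol(q$labels))
  m[q$labels == ear_idx] <- 1L
  m
}

#' Morphological cleanup of the ear mask
#'
#' Binary opening with a rectangular 6 x 6 structuring element removes
#' background specks and burrs around the ears; a 3 x 3 closing then fills
#' small holes inside them.
#'
#' @param mask binary integer matrix (0/1).
#' @param cfg a [seg_config()]; `open_kernel` and `close_kernel` are used.
#' @return the cleaned binary mask, same size.
#' @export
morph_clean <- function(mask, cfg = seg_config()) {
  mask <- as_mask(mask)
  ok <- cfg$open_kernel; ck <- cfg$close_kernel
  opened <- cpp_dilate(cpp_erode(mask, ok[1], ok[2]), ok[1], ok[2])
  cpp_erode(cpp_dilate(opened, ck[1], ck[2]), ck[1], ck[2])
}

as_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  storage.mode(mask) <- "integer"
  mask
}

#' Extract candidate ear regions
#'
#' 8-connected components of the mask's foreground; components smaller than
#' `min_area` are discarded. Coordinates are 0-based with half-open
#' bounding boxes; the perimeter is the length of the outer Moore boundary
#' contour (diagonal steps weighted `sqrt(2)`).
#'
#' @param mask binary integer matrix.
#' @param cfg a [seg_config()]; `min_area` is used.
#' @return a tibble with one row per region, ordered by `(row_min, col_min)`:
#'   `region_id`, `row_min`, `col_min`, `height`, `width`, `centroid_row`,
#'   `centroid_col`, `area`, `perimeter`.
#' @export
extract_regions <- function(mask, cfg = seg_config()) {
  mask <- as_mask(mask)
  lab <- cpp_label8(mask)
  n <- max(lab)
  if (n == 0L) return(empty_regions())
  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(lab)       # 0-based rows
  cc <- (idx - 1L) %/% nrow(lab)     # 0-based cols
  area <- tabulate(l, nbins = n)
  keep <- which(area >= cfg$min_area)
  if (length(keep) == 0L) return(empty_regions())
  per <- cpp_perimeter(lab, n)
  reg <- tibble::tibble(
    region_id = keep,
    row_min = as.integer(tapply(r, l, min)[keep]),
    col_min = as.integer(tapply(cc, l, min)[keep]),
    height = as.integer(tapply(r, l, max)[keep]) -
      as.integer(tapply(r, l, min)[keep]) + 1L,
    width = as.integer(tapply(cc, l, max)[keep]) -
      as.integer(tapply(cc, l, min)[keep]) + 1L,
    centroid_row = as.numeric(tapply(r, l, mean)[keep]),
    centroid_col = as.numeric(tapply(cc, l, mean)[keep]),
    area = area[keep],
    perimeter = per[keep]
  )
  reg <- reg[order(reg$row_min, reg$col_min), ]
  reg$region_id <- seq_len(nrow(reg))
  reg
}

empty_regions <- function() {
  tibble::tibble(region_id = integer(0), row_min = integer(0),
                 col_min = integer(0), height = integer(0), width = integer(0),
                 centroid_row = double(0), centroid_col = double(0),
                 area = integer(0), perimeter = double(0))
}

#' Pad an image with a constant border
#'
#' A border keeps ears that touch the frame edge separable; downstream
#' region coordinates are reported in the padded frame.
#'
#' @param img an [rgb_image()].
#' @param width border width in pixels (>= 0).
#' @param value length-3 RGB fill colour (default black).
#' @return the padded [rgb_image()], `(H + 2 width) x (W + 2 width)`.
#' @export
pad_border <- function(img, width, value = c(0, 0, 0)) {
  img <- as_rgb_image(img)
  stopifnot(width >= 0, length(value) == 3L)
  if (width == 0) return(img)
  H <- img_height(img); W <- img_width(img)
  out <- array(rep(value, each = (H + 2 * width) * (W + 2 * width)),
               c(H + 2 * width, W + 2 * width, 3L))
  out[(width + 1L):(width + H), (width + 1L):(width + W), ] <- unclass(img)
  rgb_image(out)
}

pad_mask <- function(mask, width) {
  if (width == 0) return(mask)
  out <- matrix(0L, nrow(mask) + 2L * width, ncol(mask) + 2L * width)
  out[(width + 1L):(width + nrow(mask)),
      (width + 1L):(width + ncol(mask))] <- mask
  out
}

#' Crop classifier patches for a set of regions
#'
#' Each bounding box is expanded by `bbox_margin` on every side (clipped at
#' the frame), cropped from the colour image, and bilinearly resized to
#' `patch_size` (aspect ratio not preserved).
#'
#' @param img the (enhanced, padded) colour [rgb_image()] the region
#'   coordinates refer to.
#' @param regions a region tibble from [extract_regions()].
#' @param cfg a [seg_config()]; `bbox_margin` and `patch_size` are used.
#' @return a list of `patch_size` [rgb_image()] patches, one per region,
#'   in region order.
#' @export
crop_patches <- function(img, regions, cfg = seg_config()) {
  img <- as_rgb_image(img)
  H <- img_height(img); W <- img_width(img)
  m <- cfg$bbox_margin
  lapply(seq_len(nrow(regions)), function(i) {
    r0 <- max(0L, regions$row_min[i] - m)
    c0 <- max(0L, regions$col_min[i] - m)
    r1 <- min(H, regions$row_min[i] + regions$height[i] + m)  # half-open
    c1 <- min(W, regions$col_min[i] + regions$width[i] + m)
    crop <- rgb_image(unclass(img)[(r0 + 1L):r1, (c0 + 1L):c1, , drop = FALSE])
    resize_image(crop, cfg$patch_size[1], cfg$patch_size[2])
  })
}

#' Segment an enhanced image into candidate ear regions and patches
#'
#' The full segmentation stage: K-means colour quantization, ear-cluster
#' selection, binarization, morphological cleanup, protective border
#' padding, 8-connected region extraction, and patch cropping.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param img an enhanced [rgb_image()] (see [preprocess_image()]).
#' @param cfg a [seg_config()].
#' @return a list of class `segmentation`: `regions` (tibble, coordinates in
#'   the padded frame), `patches` (list of patch images), `mask` (cleaned
#'   binary mask, unpadded frame), `quantized` (the `quantized_image`),
#'   `ear_cluster` (0-based index), `border_pad` (pixels).
#' @export
segment_image <- function(img, cfg = seg_config()) {
  img <- as_rgb_image(img)
  q <- kmeans_quantize(img, cfg)
  ear <- select_ear_cluster(q)
  mask <- binarize(q, ear)
  if (q$centers[ear + 1L, 3] - min(q$centers[, 3]) < cfg$min_yellow_margin) {
    mask[] <- 0L  # no cluster is distinctly yellow: treat as ear-free
  }
  clean <- morph_clean(mask, cfg)
  # fill colour: the dominant non-ear (background) cluster centre
  counts <- tabulate(as.vector(q$labels) + 1L, nbins = q$k)
  bg <- order(counts, decreasing = TRUE)
  bg <- bg[bg != (ear + 1L)][1L]
  fill <- as.vector(lab_to_rgb(array(q$centers[bg, ], c(1, 1, 3))))
  padded_img <- pad_border(img, cfg$border_pad, fill)
  padded_mask <- pad_mask(clean, cfg$border_pad)
  regions <- extract_regions(padded_mask, cfg)
  patches <- crop_patches(padded_img, regions, cfg)
  structure(list(regions = regions, patches = patches, mask = clean,
                 quantized = q, ear_cluster = ear,
                 border_pad = cfg$border_pad),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation: %d candidate region(s), ear cluster %d>\n",
              nrow(x$regions), x$ear_cluster))
  invisible(x)
}

#' Draw region bounding boxes on an image
#'
#' Renders the detections the way a field operator inspects them: boxes
#' around every candidate ear region, in the coordinate frame the regions
#' were measured in.
#'
#' @param img the [rgb_image()] the coordinates refer to (after padding if
#'   the regions came from [segment_image()]).
#' @param regions a region tibble.
#' @param color length-3 RGB draw colour.
#' @param thickness line thickness in pixels.
#' @return an [rgb_image()] with boxes drawn.
#' @export
render_overlay <- function(img, regions, color = c(255, 40, 40),
                           thickness = 2L) {
  img <- unclass(as_rgb_image(img))
  H <- dim(img)[1]; W <- dim(img)[2]
  for (i in seq_len(nrow(regions))) {
    r0 <- regions$row_min[i] + 1L
    c0 <- regions$col_min[i] + 1L
    r1 <- min(H, r0 + regions$height[i] - 1L)
    c1 <- min(W, c0 + regions$width[i] - 1L)
    for (t in seq_len(thickness) - 1L) {
      rows <- c(max(1L, r0 - t), min(H, r1 + t))
      cols <- c(max(1L, c0 - t), min(W, c1 + t))
      for (ch in 1:3) {
        img[rows, cols[1]:cols[2], ch] <- color[ch]
        img[rows[1]:rows[2], cols, ch] <- color[ch]
      }
    }
  }
  rgb_image(img)
}
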