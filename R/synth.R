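#' Synthetic canopy scene configuration
#'
#' Emulates a nadir view of a wheat canopy at grain filling: a brown soil
#' base, green leaf/stem strokes as clutter, and yellow ears rendered as
#' speckle-textured ellipses. A fraction of the ears is placed as fused
#' groups of 2--3 overlapping ellipses forming a single connected blob,
#' reproducing the adhesion that motivates the 0/1/2/3-ear label space.
#' The default "easy regime" palettes are well separated in CIELAB so the
#' segmentation stack can isolate the ear cluster; lowering the separation
#' (e.g. greening the ears) emulates the early grain-filling stage.
#'
#' @param size integer length-2 scene size `c(H, W)`.
#' @param n_ears total number of ears in the scene.
#' @param adhesion fraction of ears placed in fused groups (0--1).
#' @param fuse_sizes group sizes to sample for fused blobs (subset of 2:3).
#' @param palettes list with `ear`, `leaf`, `soil`, each
#'   `list(mean = RGB, sd = scalar)`.
#' @param ear_major,ear_minor ellipse full-axis ranges in pixels.
#' @param clutter number of leaf strokes.
#' @param noise_sd additive Gaussian intensity noise (0--255 scale).
#' @param speckle_sd per-pixel ear texture noise.
#' @param min_sep minimum gap between distinct blobs, in pixels.
#' @param max_attempts placement rejection-sampling budget per blob.
#' @param seed RNG seed; scenes are bit-reproducible given the seed.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(size = c(700L, 700L), n_ears = 20L, adhesion = 0,
                         fuse_sizes = 2:3,
                         palettes = default_palettes(),
                         ear_major = c(30, 60), ear_minor = c(10, 20),
                         clutter = 40L, noise_sd = 4, speckle_sd = 10,
                         min_sep = 12, max_attempts = 500L, seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 1), n_ears >= 0,
            adhesion >= 0, adhesion <= 1, all(fuse_sizes %in% 2:3),
            length(ear_major) == 2L, length(ear_minor) == 2L,
            ear_major[1] <= ear_major[2], ear_minor[1] <= ear_minor[2],
            clutter >= 0, noise_sd >= 0, speckle_sd >= 0, min_sep >= 0,
            max_attempts >= 1)
  structure(list(size = as.integer(size), n_ears = as.integer(n_ears),
                 adhesion = adhesion, fuse_sizes = as.integer(fuse_sizes),
                 palettes = palettes, ear_major = ear_major,
                 ear_minor = ear_minor, clutter = as.integer(clutter),
                 noise_sd = noise_sd, speckle_sd = speckle_sd,
                 min_sep = min_sep, max_attempts = as.integer(max_attempts),
                 seed = seed),
            class = "scene_config")
}

#' @rdname scene_config
#' @export
default_palettes <- function() {
  list(ear = list(mean = c(210, 185, 90), sd = 8),
       leaf = list(mean = c(70, 135, 60), sd = 12),
       soil = list(mean = c(125, 100, 70), sd = 10))
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# fill an ellipse (centre cr/cc, full axes major/minor, angle radians) into
# channel planes; returns the logical membership matrix restricted to a bbox
ellipse_pixels <- function(H, W, cr, cc, major, minor, angle) {
  a <- major / 2; b <- minor / 2
  ext <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(cr - ext)); r1 <- min(H, ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(W, ceiling(cc + ext))
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  ccv <- rep(c0:c1, each = r1 - r0 + 1L)
  x <- rr - cr; y <- ccv - cc
  u <- cos(angle) * x + sin(angle) * y
  v <- -sin(angle) * x + cos(angle) * y
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(NULL)
  cbind(row = rr[inside], col = ccv[inside])
}

plan_blobs <- function(n_ears, adhesion, fuse_sizes) {
  n_fused <- round(adhesion * n_ears)
  mult <- integer(0)
  while (n_fused >= 2L) {
    s <- if (length(fuse_sizes) == 1L) fuse_sizes else sample(fuse_sizes, 1L)
    s <- min(s, n_fused)
    if (s < 2L) break
    mult <- c(mult, s)
    n_fused <- n_fused - s
  }
  c(mult, rep(1L, n_ears - sum(mult)))
}

#' Generate a synthetic canopy scene with known truth
#'
#' @param cfg a [scene_config()].
#' @return a list of class `scene`: `image` (an [rgb_image()]), `truth`
#'   (list with `total_ears`, `blobs` tibble of per-blob centroid /
#'   multiplicity / area, and `blob_map`, an integer `H x W` matrix of blob
#'   ids with 0 for background).
#' @export
generate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, render_scene(cfg))
}

render_scene <- function(cfg, n_ears = cfg$n_ears) {
  H <- cfg$size[1]; W <- cfg$size[2]
  pal <- cfg$palettes
  img <- array(0, c(H, W, 3L))
  npix <- H * W
  for (ch in 1:3) {
    img[, , ch] <- pal$soil$mean[ch] + rnorm(npix, 0, pal$soil$sd)
  }
  # leaf/stem clutter: elongated green strokes
  for (s in seq_len(cfg$clutter)) {
    shade <- pal$leaf$mean + rnorm(3, 0, pal$leaf$sd)
    px <- ellipse_pixels(H, W, runif(1, 1, H), runif(1, 1, W),
                         major = runif(1, 40, 120), minor = runif(1, 4, 12),
                         angle = runif(1, 0, pi))
    if (is.null(px)) next
    for (ch in 1:3) {
      img[, , ch][px] <- clamp255(shade[ch] + rnorm(nrow(px), 0, 6))
    }
  }
  # ears: plan blob multiplicities, then place blobs with rejection sampling
  mult <- plan_blobs(n_ears, cfg$adhesion, cfg$fuse_sizes)
  blob_map <- matrix(0L, H, W)
  placed_r <- double(0); placed_c <- double(0); placed_rad <- double(0)
  blobs <- list()
  for (bi in seq_along(mult)) {
    k <- mult[bi]
    major <- runif(k, cfg$ear_major[1], cfg$ear_major[2])
    minor <- runif(k, cfg$ear_minor[1], cfg$ear_minor[2])
    # bounding radius: first ellipse plus perpendicular offsets of the others
    span <- max(major) / 2 + if (k > 1) sum(0.75 * (minor[-k] + minor[-1]) / 2) else 0
    rad <- span + 2
    ok <- FALSE
    for (att in seq_len(cfg$max_attempts)) {
      cr <- runif(1, rad + 1, H - rad)
      cc <- runif(1, rad + 1, W - rad)
      if (length(placed_r) == 0L ||
          all(sqrt((placed_r - cr)^2 + (placed_c - cc)^2) >=
              placed_rad + rad + cfg$min_sep)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(
        "could not place blob %d after %d attempts; reduce n_ears or sizes",
        bi, cfg$max_attempts), call. = FALSE)
    }
    angle <- runif(1, 0, pi)
    # fused ears sit side by side: offset roughly perpendicular to the axis
    offs_r <- 0; offs_c <- 0
    for (e in seq_len(k)) {
      if (e > 1L) {
        d <- 0.75 * (minor[e - 1] + minor[e]) / 2
        dir <- angle + pi / 2 + runif(1, -0.3, 0.3)
        offs_r <- offs_r + d * cos(dir)
        offs_c <- offs_c + d * sin(dir)
      }
      shade <- pal$ear$mean + rnorm(3, 0, pal$ear$sd)
      px <- ellipse_pixels(H, W, cr + offs_r, cc + offs_c, major[e], minor[e],
                           angle + runif(1, -0.2, 0.2))
      if (is.null(px)) next
      for (ch in 1:3) {
        img[, , ch][px] <- clamp255(shade[ch] + rnorm(nrow(px), 0, cfg$speckle_sd))
      }
      blob_map[px] <- bi
    }
    placed_r <- c(placed_r, cr); placed_c <- c(placed_c, cc)
    placed_rad <- c(placed_rad, rad)
    idx <- which(blob_map == bi)
    blobs[[bi]] <- tibble::tibble(
      blob = bi,
      centroid_row = mean((idx - 1L) %% H),
      centroid_col = mean((idx - 1L) %/% H),
      multiplicity = k,
      area = length(idx)
    )
  }
  if (cfg$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim(img))
  }
  image <- rgb_image(round(clamp255(img)))
  truth <- list(
    total_ears = sum(mult),
    blobs = if (length(blobs)) dplyr::bind_rows(blobs) else
      tibble::tibble(blob = integer(0), centroid_row = double(0),
                     centroid_col = double(0), multiplicity = integer(0),
                     area = integer(0)),
    blob_map = blob_map
  )
  structure(list(image = image, truth = truth, cfg = cfg), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene %d x %d: %d ears in %d blob(s)>\n",
              nrow(x$truth$blob_map), ncol(x$truth$blob_map),
              x$truth$total_ears, nrow(x$truth$blobs)))
  invisible(x)
}

#' Scene size for a target ear count at canopy density
#'
#' Nadir canopy imagery has a roughly constant ear density, so a sampling
#' window that contains few ears is smaller than one containing many. This
#' helper returns the square window side that holds `n_ears` at a given
#' ear-pixel fraction, given the configured ear geometry.
#'
#' @param n_ears number of ears the window should hold.
#' @param cfg a [scene_config()]; the ellipse axis ranges set the mean ear
#'   area.
#' @param ear_fraction target fraction of window pixels covered by ears.
#' @param min_side,max_side clamp for the window side, in pixels.
#' @return integer window side.
#' @export
scene_size_for <- function(n_ears, cfg = scene_config(),
                           ear_fraction = 0.05,
                           min_side = 250L, max_side = 700L) {
  mean_area <- pi / 4 * mean(cfg$ear_major) * mean(cfg$ear_minor)
  side <- ceiling(sqrt(max(1, n_ears) * mean_area / ear_fraction))
  as.integer(min(max(side, min_side), max_side))
}

#' Generate a labeled synthetic patch dataset
#'
#' Builds balanced 100 x 100 classifier patches the same way the real
#' pipeline produces them: a small canopy tile is rendered (soil + leaf
#' clutter, plus one fused blob of 1--3 ears for the positive classes),
#' passed through [enhance()], and the blob's bounding box (plus margin) is
#' cropped and resized to the patch size. Class 0 patches are
#' background-only crops.
#'
#' @param per_class patches per class (4 classes).
#' @param cfg a [scene_config()]; palettes, ear geometry, clutter and noise
#'   are taken from it, and `cfg$seed` makes the build reproducible.
#' @param enhance_patches apply the standard enhancement (as the pipeline
#'   does before cropping); keep `TRUE` for training data that matches
#'   pipeline patches.
#' @param bbox_margin,patch_size cropping geometry, as in [seg_config()].
#' @param keep_truth also return the pre-resize blob masks (for tests).
#' @return a [patch_set()]; if `keep_truth`, with a `truth_masks` attribute
#'   (list of binary matrices, `NULL` for class 0).
#' @export
generate_patch_dataset <- function(per_class, cfg = scene_config(),
                                   enhance_patches = TRUE,
                                   bbox_margin = 4L,
                                   patch_size = c(100L, 100L),
                                   keep_truth = FALSE) {
  stopifnot(per_class >= 1)
  with_seed(cfg$seed, {
    tile <- ceiling(2.2 * cfg$ear_major[2])
    tile_cfg <- cfg
    tile_cfg$size <- c(tile, tile)
    tile_cfg$clutter <- max(1L, min(3L, cfg$clutter))
    patches <- list(); labels <- integer(0); ids <- character(0)
    masks <- list()
    for (klass in 0:3) {
      for (i in seq_len(per_class)) {
        sc <- render_patch_tile(tile_cfg, klass)
        img <- sc$image
        if (enhance_patches) img <- enhance(img)
        mask <- sc$truth$blob_map > 0
        if (klass == 0L) {
          # background candidates at count time are blob bounding boxes of
          # widely varying size blown up to the patch size; emulate that
          # zoom distribution instead of always cropping the full tile
          side <- sample(20:min(tile, 120L), 1L)
          r0 <- sample.int(tile - side + 1L, 1L) - 1L
          c0 <- sample.int(tile - side + 1L, 1L) - 1L
          r1 <- r0 + side; c1 <- c0 + side
        } else {
          idx <- which(mask)
          r <- (idx - 1L) %% tile; cc <- (idx - 1L) %/% tile
          r0 <- max(0L, min(r) - bbox_margin)
          c0 <- max(0L, min(cc) - bbox_margin)
          r1 <- min(tile, max(r) + 1L + bbox_margin)
          c1 <- min(tile, max(cc) + 1L + bbox_margin)
        }
        crop <- rgb_image(unclass(img)[(r0 + 1L):r1, (c0 + 1L):c1, ,
                                       drop = FALSE])
        patches[[length(patches) + 1L]] <-
          resize_image(crop, patch_size[1], patch_size[2])
        labels <- c(labels, klass)
        ids <- c(ids, sprintf("synth_%d_%04d", klass, i))
        if (keep_truth) {
          masks[length(masks) + 1L] <- list(
            if (klass == 0L) NULL else
              mask[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE])
        }
      }
    }
    ps <- patch_set(patches, labels, ids)
    if (keep_truth) attr(ps, "truth_masks") <- masks
    ps
  })
}

# one tile with exactly `klass` ears in a single centred fused blob
render_patch_tile <- function(tile_cfg, klass) {
  tcfg <- tile_cfg
  tcfg$n_ears <- klass
  tcfg$adhesion <- if (klass >= 2L) 1 else 0
  tcfg$fuse_sizes <- if (klass >= 2L) klass else tile_cfg$fuse_sizes
  # centre the blob: shrink placement jitter by using a large min_sep-free
  # single placement (the scene placer already rejection-samples inside the
  # frame; with one blob it succeeds immediately)
  render_scene(tcfg)
}

#' Write synthetic scenes to a directory
#'
#' Writes `scene_###.png` files plus `truth.csv` (image_id, n_ears, blobs).
#'
#' @param n number of scenes.
#' @param cfg a [scene_config()] template; scene `i` uses seed
#'   `stage_seed(cfg$seed, paste0("scene", i))`.
#' @param ears integer length-2 range for per-scene ear counts.
#' @param dir output directory.
#' @return the truth tibble, invisibly.
#' @export
write_scenes <- function(n, cfg, ears = c(5L, 40L), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cfg
    ci$seed <- stage_seed(cfg$seed, paste0("scene", i))
    ci$n_ears <- with_seed(ci$seed + 1L,
                           sample(seq(ears[1], ears[2]), 1L))
    sc <- generate_scene(ci)
    id <- sprintf("scene_%03d.png", i)
    save_image(sc$image, file.path(dir, id))
    rows[[i]] <- tibble::tibble(image_id = id, n_ears = sc$truth$total_ears,
                                n_blobs = nrow(sc$truth$blobs))
  }
  truth <- dplyr::bind_rows(rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}
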