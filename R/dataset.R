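#' Labeled patch sets
#'
#' A `patch_set` holds 100 x 100 classifier patches with their ear-count
#' labels (0--3) and a provenance id per patch. Patches are stored as
#' integer `H x W x 3` arrays in `[0, 255]`.
#'
#' @param patches list of patch arrays.
#' @param labels integer vector in `{0, 1, 2, 3}`, one per patch.
#' @param source_id character vector, one per patch; augmented copies share
#'   the id of their source patch.
#' @return an object of class `patch_set`.
#' @export
patch_set <- function(patches, labels, source_id = as.character(seq_along(patches))) {
  stopifnot(is.list(patches), length(patches) == length(labels),
            length(source_id) == length(patches))
  labels <- as.integer(labels)
  if (length(labels) && (anyNA(labels) || any(labels < 0L | labels > 3L))) {
    stop("labels must be in {0, 1, 2, 3}", call. = FALSE)
  }
  patches <- lapply(patches, function(p) {
    p <- unclass(as_rgb_image(p))
    storage.mode(p) <- "integer"
    p
  })
  structure(list(patches = patches, labels = labels,
                 source_id = as.character(source_id)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf("<patch_set: %d patches; per-class counts %s>\n",
              length(x$labels), paste(tab, collapse = "/")))
  invisible(x)
}

#' @export
length.patch_set <- function(x) length(x$labels)

#' @rdname patch_set
#' @param x a `patch_set`.
#' @param ... unused.
#' @export
tidy.patch_set <- function(x, ...) {
  tibble::tibble(patch = seq_along(x$labels), label = x$labels,
                 source_id = x$source_id)
}

class_dir_names <- c("0_ears", "1_ear", "2_ears", "3_ears")

#' Load labeled patches from a class-per-directory layout
#'
#' `root` must contain the subdirectories `0_ears/`, `1_ear/`, `2_ears/`,
#' `3_ears/` of PNG (or JPEG) patches; the label is taken from the
#' directory name. Patches that are not `patch_size` are resized.
#' Non-image files are skipped with a warning.
#'
#' @param root dataset directory.
#' @param patch_size integer length-2 target size (default 100 x 100).
#' @return a [patch_set()].
#' @export
load_labeled_patches <- function(root, patch_size = c(100L, 100L)) {
  if (!dir.exists(root)) stop("no such dataset directory: ", root, call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (length(dirs) == 0L) stop("empty dataset root: ", root, call. = FALSE)
  unknown <- setdiff(dirs, class_dir_names)
  if (length(unknown)) {
    stop("unknown class directory: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  patches <- list(); labels <- integer(0); ids <- character(0)
  for (d in intersect(class_dir_names, dirs)) {
    lab <- as.integer(substr(d, 1L, 1L))
    files <- sort(list.files(file.path(root, d), full.names = TRUE))
    for (f in files) {
      p <- tryCatch(load_image(f), error = function(e) NULL)
      if (is.null(p)) {
        warning("skipping non-image file: ", f, call. = FALSE)
        next
      }
      if (!all(dim(p)[1:2] == patch_size)) {
        p <- resize_image(p, patch_size[1], patch_size[2])
      }
      patches[[length(patches) + 1L]] <- p
      labels <- c(labels, lab)
      ids <- c(ids, file.path(d, basename(f)))
    }
  }
  if (length(patches) == 0L) stop("no patches found under ", root, call. = FALSE)
  patch_set(patches, labels, ids)
}

#' Augmentation configuration
#'
#' The augmentations emulate nuisance variation in field imagery: random
#' cropping (framing), horizontal/vertical flips and rotation (ears have no
#' preferred orientation in nadir views), and multiplicative brightness
#' (illumination). Applied in that order; the label is never changed.
#'
#' @param crop_fraction area fraction retained by the random crop, in (0, 1].
#' @param allow_hflip,allow_vflip allow the respective flips.
#' @param rotation_degrees symmetric rotation range (degrees); 0 disables.
#' @param brightness_range multiplicative range, e.g. `c(0.7, 1.3)`.
#' @param seed optional RNG seed used by [balance_and_split()].
#' @return a list of class `augmentation_config`.
#' @export
augmentation_config <- function(crop_fraction = 0.9, allow_hflip = TRUE,
                                allow_vflip = TRUE, rotation_degrees = 30,
                                brightness_range = c(0.7, 1.3), seed = NULL) {
  stopifnot(crop_fraction > 0, crop_fraction <= 1,
            rotation_degrees >= 0, rotation_degrees <= 180,
            length(brightness_range) == 2L, all(brightness_range > 0),
            brightness_range[1] <= brightness_range[2])
  structure(list(crop_fraction = crop_fraction, allow_hflip = allow_hflip,
                 allow_vflip = allow_vflip,
                 rotation_degrees = rotation_degrees,
                 brightness_range = brightness_range, seed = seed),
            class = "augmentation_config")
}

# Rotate by `angle` degrees about the centre, bilinear sampling with
# edge-replicated (clamped) source coordinates.
rotate_patch <- function(img, angle) {
  if (angle == 0) return(img)
  img <- unclass(as_rgb_image(img))
  H <- dim(img)[1]; W <- dim(img)[2]
  th <- angle * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  i <- rep(seq_len(H), times = W) - cr
  j <- rep(seq_len(W), each = H) - cc
  sr <- cos(th) * i + sin(th) * j + cr
  sc <- -sin(th) * i + cos(th) * j + cc
  sr <- pmin(pmax(sr, 1), H)
  sc <- pmin(pmax(sc, 1), W)
  r0 <- floor(sr); c0 <- floor(sc)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- sr - r0; fc <- sc - c0
  out <- array(0, dim(img))
  for (ch in 1:3) {
    plane <- img[, , ch]
    v <- (1 - fr) * (1 - fc) * plane[cbind(r0, c0)] +
      (1 - fr) * fc * plane[cbind(r0, c1)] +
      fr * (1 - fc) * plane[cbind(r1, c0)] +
      fr * fc * plane[cbind(r1, c1)]
    out[, , ch] <- v
  }
  rgb_image(pmin(pmax(out, 0), 255))
}

#' Augment one labeled patch
#'
#' Applies, in order: random crop to `crop_fraction` of the area (resized
#' back to the original size), random flips, rotation sampled uniformly in
#' `[-rotation_degrees, rotation_degrees]` with edge-replicated fill, and a
#' multiplicative brightness factor with clipping to `[0, 255]`.
#' Deterministic given the R RNG state (seed it with `set.seed()` or via
#' the `seed` of [augmentation_config()] in [balance_and_split()]).
#'
#' @param patch a patch image (`H x W x 3`, values 0--255).
#' @param cfg an [augmentation_config()].
#' @return the augmented patch ([rgb_image()], same size).
#' @export
augment_patch <- function(patch, cfg = augmentation_config()) {
  patch <- as_rgb_image(patch)
  H <- img_height(patch); W <- img_width(patch)
  out <- patch
  if (cfg$crop_fraction < 1) {
    side <- sqrt(cfg$crop_fraction)
    ch <- max(1L, round(H * side)); cw <- max(1L, round(W * side))
    r0 <- sample.int(H - ch + 1L, 1L) - 1L
    c0 <- sample.int(W - cw + 1L, 1L) - 1L
    out <- rgb_image(unclass(out)[(r0 + 1L):(r0 + ch),
                                  (c0 + 1L):(c0 + cw), , drop = FALSE])
    out <- resize_image(out, H, W)
  }
  if (cfg$allow_hflip && runif(1) < 0.5) {
    out <- rgb_image(unclass(out)[, rev(seq_len(W)), , drop = FALSE])
  }
  if (cfg$allow_vflip && runif(1) < 0.5) {
    out <- rgb_image(unclass(out)[rev(seq_len(H)), , , drop = FALSE])
  }
  if (cfg$rotation_degrees > 0) {
    ang <- runif(1, -cfg$rotation_degrees, cfg$rotation_degrees)
    out <- rotate_patch(out, ang)
  }
  b <- runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
  if (b != 1) out <- rgb_image(pmin(pmax(unclass(out) * b, 0), 255))
  out
}

#' Balance classes by augmentation and split train/test
#'
#' Each class is grown to exactly `per_class` patches (originals first, then
#' augmented copies of randomly chosen class sources), of which
#' `test_per_class` are held out. The split is by *source* patch before
#' augmentation, so augmented copies of one source never straddle the
#' train/test boundary (no leakage).
#'
#' @param ps a [patch_set()] of source patches.
#' @param per_class total patches per class after balancing (default 12000).
#' @param test_per_class held-out patches per class (default 1000).
#' @param cfg an [augmentation_config()]; its `seed` makes the build
#'   reproducible.
#' @return an object of class `patch_dataset`: list with `train` and `test`
#'   [patch_set()]s and a `per_class_counts` tibble.
#' @export
balance_and_split <- function(ps, per_class = 12000L, test_per_class = 1000L,
                              cfg = augmentation_config()) {
  stopifnot(inherits(ps, "patch_set"), per_class >= 1,
            test_per_class >= 0, test_per_class < per_class)
  with_seed(cfg$seed, {
    tr_p <- list(); tr_l <- integer(0); tr_s <- character(0)
    te_p <- list(); te_l <- integer(0); te_s <- character(0)
    for (klass in 0:3) {
      sel <- which(ps$labels == klass)
      if (length(sel) == 0L) {
        stop(sprintf("class %d has no source patches", klass), call. = FALSE)
      }
      src_ids <- unique(ps$source_id[sel])
      src_ids <- sample(src_ids)
      n_test_src <- max(if (test_per_class > 0) 1L else 0L,
                        round(length(src_ids) * test_per_class / per_class))
      n_test_src <- min(n_test_src, length(src_ids) - 1L)
      if (test_per_class > 0 && n_test_src < 1L) {
        stop(sprintf(paste("class %d has %d source patch(es); at least 2 are",
                           "needed for a source-disjoint test split"),
                     klass, length(src_ids)), call. = FALSE)
      }
      test_src <- utils::head(src_ids, n_test_src)
      train_src <- setdiff(src_ids, test_src)
      fill <- function(pool_src, target) {
        pool <- sel[ps$source_id[sel] %in% pool_src]
        out_p <- list(); out_l <- integer(0); out_s <- character(0)
        n_orig <- min(length(pool), target)
        take <- pool[seq_len(n_orig)]
        for (i in take) {
          out_p[[length(out_p) + 1L]] <- ps$patches[[i]]
        }
        out_l <- rep(klass, n_orig)
        out_s <- ps$source_id[take]
        while (length(out_p) < target) {
          i <- pool[sample.int(length(pool), 1L)]
          out_p[[length(out_p) + 1L]] <-
            unclass(augment_patch(ps$patches[[i]], cfg))
          out_l <- c(out_l, klass)
          out_s <- c(out_s, ps$source_id[i])
        }
        list(p = out_p, l = out_l, s = out_s)
      }
      te <- fill(test_src, test_per_class)
      tr <- fill(train_src, per_class - test_per_class)
      tr_p <- c(tr_p, tr$p); tr_l <- c(tr_l, tr$l); tr_s <- c(tr_s, tr$s)
      te_p <- c(te_p, te$p); te_l <- c(te_l, te$l); te_s <- c(te_s, te$s)
    }
    train <- patch_set(tr_p, tr_l, tr_s)
    test <- patch_set(te_p, te_l, te_s)
    counts <- tibble::tibble(
      class = 0:3,
      train = tabulate(train$labels + 1L, 4L),
      test = tabulate(test$labels + 1L, 4L)
    )
    structure(list(train = train, test = test, per_class_counts = counts),
              class = "patch_dataset")
  })
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset: %d train, %d test>\n",
              length(x$train), length(x$test)))
  print(x$per_class_counts)
  invisible(x)
}

#' @rdname balance_and_split
#' @param x a `patch_dataset`.
#' @param ... unused.
#' @export
tidy.patch_dataset <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$train), split = "train"),
    dplyr::mutate(tidy(x$test), split = "test")
  )
}

#' Write a patch set to a class-per-directory layout
#'
#' Writes PNG patches under `0_ears/ .. 3_ears/` plus a `manifest.csv`
#' (path, label, split, source_id, augmentation_seed).
#'
#' @param ps a [patch_set()].
#' @param dir output directory (created if needed).
#' @param split split name recorded in the manifest (e.g. `"train"`).
#' @param augmentation_seed seed recorded in the manifest, if any.
#' @return `dir`, invisibly.
#' @export
write_patch_set <- function(ps, dir, split = NA_character_,
                            augmentation_seed = NA_integer_) {
  stopifnot(inherits(ps, "patch_set"))
  for (d in class_dir_names) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  paths <- character(length(ps$labels))
  for (i in seq_along(ps$labels)) {
    d <- class_dir_names[ps$labels[i] + 1L]
    paths[i] <- file.path(d, sprintf("patch_%05d.png", i))
    save_image(ps$patches[[i]], file.path(dir, paths[i]))
  }
  manifest <- tibble::tibble(path = paths, label = ps$labels,
                             split = split, source_id = ps$source_id,
                             augmentation_seed = augmentation_seed)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
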