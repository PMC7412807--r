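#' Turn patch labels into an ear count
#'
#' The count is classify-then-sum: every candidate region labelled 1, 2 or
#' 3 contributes that many ears; regions labelled 0 (reflective leaves and
#' other non-ear blobs) contribute nothing, which is the pipeline's
#' false-positive suppression. Blobs fusing more than three ears are
#' outside the label space and are undercounted by design.
#'
#' @param labels integer vector of per-region class labels in `{0,1,2,3}`.
#' @param image_id identifier copied into the result.
#' @return a one-row tibble: `image_id`, `region_count`, `tally_0` ..
#'   `tally_3`, `predicted_count`, `manual_count` (`NA` until attached).
#' @export
count_from_labels <- function(labels, image_id = NA_character_) {
  labels <- as.integer(labels)
  if (length(labels) && (anyNA(labels) || any(labels < 0L | labels > 3L))) {
    stop("labels must be in {0, 1, 2, 3}", call. = FALSE)
  }
  tally <- tabulate(labels + 1L, nbins = 4L)
  tibble::tibble(
    image_id = as.character(image_id),
    region_count = length(labels),
    tally_0 = tally[1], tally_1 = tally[2],
    tally_2 = tally[3], tally_3 = tally[4],
    predicted_count = sum(labels),
    manual_count = NA_integer_
  )
}

#' Count the ears in one image
#'
#' Runs the full pipeline: preprocessing ([preprocess_image()]),
#' segmentation ([segment_image()]), patch classification
#' ([predict.ear_cnn()]), and label summation ([count_from_labels()]).
#' Deterministic given the seeds in the configurations.
#'
#' @param img an [rgb_image()] or a path to one.
#' @param model a trained `ear_cnn`.
#' @param seg_cfg a [seg_config()].
#' @param prep_cfg a [preprocess_config()].
#' @param image_id identifier for the result row.
#' @return a one-row count tibble as in [count_from_labels()].
#' @export
count_image <- function(img, model, seg_cfg = seg_config(),
                        prep_cfg = preprocess_config(crop = NULL, scale = NULL),
                        image_id = NA_character_) {
  if (is.character(img)) {
    if (is.na(image_id)) image_id <- basename(img)
    img <- load_image(img)
  }
  pre <- preprocess_image(img, prep_cfg)
  seg <- segment_image(pre, seg_cfg)
  if (length(seg$patches) == 0L) {
    return(count_from_labels(integer(0), image_id))
  }
  pred <- predict(model, seg$patches)
  count_from_labels(pred$label, image_id)
}

#' Count a batch of images and attach manual counts
#'
#' @param paths character vector of image paths.
#' @param model a trained `ear_cnn`.
#' @param seg_cfg,prep_cfg configurations passed to [count_image()].
#' @param manual optional manual counts: a data frame with columns
#'   `image_id` and `manual_count`, or a path to such a CSV. Missing ids
#'   get `NA` with a warning; duplicated ids keep the last row (warned).
#' @return a tibble with one row per image.
#' @export
count_batch <- function(paths, model, seg_cfg = seg_config(),
                        prep_cfg = preprocess_config(crop = NULL, scale = NULL),
                        manual = NULL) {
  res <- purrr::map_dfr(paths, function(p) {
    count_image(p, model, seg_cfg, prep_cfg, image_id = basename(p))
  })
  if (!is.null(manual)) {
    if (is.character(manual)) {
      manual <- utils::read.csv(manual, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("image_id", "manual_count") %in% names(manual)))
    if (anyDuplicated(manual$image_id)) {
      warning("duplicate image ids in manual counts; last wins",
              call. = FALSE)
      manual <- manual[!duplicated(manual$image_id, fromLast = TRUE), ]
    }
    hit <- match(res$image_id, manual$image_id)
    if (nrow(res) && anyNA(hit)) {
      warning("no manual count for: ",
              paste(res$image_id[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    res$manual_count <- as.integer(manual$manual_count[hit])
  }
  res
}
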