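#' Multiclass confusion matrix
#'
#' Rows are the true class, columns the predicted class. Per-class
#' true/false positives and false negatives derive as `TP_i = counts[i,i]`,
#' `FP_i = colsum_i - TP_i`, `FN_i = rowsum_i - TP_i`.
#'
#' @param truth,predicted integer class vectors (0-based) of equal length,
#'   or `truth` may be an `n x n` count matrix (then `predicted` is ignored).
#' @param n_classes number of classes.
#' @return an integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted = NULL, n_classes = 4L) {
  if (is.matrix(truth)) {
    m <- truth
    stopifnot(nrow(m) == ncol(m), all(m >= 0))
  } else {
    stopifnot(length(truth) == length(predicted))
    m <- matrix(0L, n_classes, n_classes)
    for (i in seq_along(truth)) {
      m[truth[i] + 1L, predicted[i] + 1L] <- m[truth[i] + 1L, predicted[i] + 1L] + 1L
    }
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(true = paste0("class_", seq_len(nrow(m)) - 1L),
                      predicted = paste0("class_", seq_len(ncol(m)) - 1L))
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(unclass(x))
  invisible(x)
}

#' @rdname confusion_matrix
#' @param x a `confusion_matrix`.
#' @param ... unused.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    true = rep(seq_len(n) - 1L, times = n),
    predicted = rep(seq_len(n) - 1L, each = n),
    n = as.integer(x)[as.vector(matrix(seq_len(n * n), n))]
  )
}

#' @rdname confusion_matrix
#' @param object a `confusion_matrix`.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$predicted),
                                  y = factor(.data$true, levels = rev(sort(unique(.data$true)))),
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "white", high = "goldenrod") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = "Confusion matrix") +
    ggplot2::theme_minimal()
}

# round half up on the percent scale, 2 decimals, as printed in field tables
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-class precision and recall
#'
#' `P_i = TP_i / (TP_i + FP_i)`, `R_i = TP_i / (TP_i + FN_i)`. A class
#' whose denominator is zero gets 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return a tibble: `class`, `precision`, `recall` (fractions in
#'   `[0, 1]`), plus `precision_pct` / `recall_pct` rounded half-up to two
#'   decimals as reported in field studies.
#' @export
precision_recall <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  pden <- tp + fp
  rden <- tp + fn
  if (any(pden == 0) || any(rden == 0)) {
    warning("class with zero denominator; precision/recall set to 0",
            call. = FALSE)
  }
  p <- ifelse(pden > 0, tp / pden, 0)
  r <- ifelse(rden > 0, tp / rden, 0)
  tibble::tibble(class = seq_len(nrow(cm)) - 1L,
                 precision = unname(p), recall = unname(r),
                 precision_pct = round_half_up(100 * unname(p)),
                 recall_pct = round_half_up(100 * unname(r)))
}

#' Per-class F1 and macro F1
#'
#' `F1_i = 2 P_i R_i / (P_i + R_i)` (0 when both are 0); the macro score is
#' the unweighted mean over classes.
#'
#' @param precision,recall numeric vectors in `[0, 1]`, or a single tibble
#'   from [precision_recall()] as the first argument.
#' @return a list with `f1` (per-class vector), `macro_f1` (scalar), and
#'   the percent renderings `f1_pct`, `macro_f1_pct`.
#' @export
f1_scores <- function(precision, recall = NULL) {
  if (is.data.frame(precision)) {
    recall <- precision$recall
    precision <- precision$precision
  }
  stopifnot(length(precision) == length(recall),
            all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  s <- precision + recall
  f1 <- ifelse(s > 0, 2 * precision * recall / s, 0)
  macro <- mean(f1)
  list(f1 = f1, macro_f1 = macro,
       f1_pct = round_half_up(100 * f1),
       macro_f1_pct = round_half_up(100 * macro))
}

#' Micro-averaged precision, recall and F1
#'
#' Pools TP/FP/FN over classes before forming the ratios. For single-label
#' multiclass data the pooled FP and FN totals coincide, so micro
#' precision, recall and F1 all equal accuracy.
#'
#' @param cm a [confusion_matrix()].
#' @return a list: `precision`, `recall`, `f1` (fractions) and `f1_pct`.
#' @export
micro_f1 <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- sum(diag(cm))
  fp <- sum(colSums(cm) - diag(cm))
  fn <- sum(rowSums(cm) - diag(cm))
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1,
       f1_pct = round_half_up(100 * f1))
}

#' Full classification metrics table
#'
#' Convenience wrapper mirroring a per-class accuracy table: per-class
#' precision/recall/F1 plus the macro and micro summaries.
#'
#' @param cm a [confusion_matrix()].
#' @return a list with `per_class` (tibble), `macro_f1`, `micro_f1`,
#'   `accuracy` (fractions).
#' @export
class_metrics <- function(cm) {
  pr <- precision_recall(cm)
  f1 <- f1_scores(pr)
  mi <- micro_f1(cm)
  per <- pr
  per$f1 <- f1$f1
  per$f1_pct <- f1$f1_pct
  list(per_class = per, macro_f1 = f1$macro_f1, micro_f1 = mi$f1,
       accuracy = sum(diag(cm)) / sum(cm))
}

#' Agreement between manual and predicted counts
#'
#' Computes, over paired per-image counts (`m` manual, `c` predicted):
#' \deqn{R^2 = 1 - \sum (m_i - c_i)^2 / \sum (m_i - \bar m)^2}
#' (evaluated against the predictions, not a squared correlation, so it can
#' be negative for a poor predictor), \deqn{RMSE = \sqrt{\frac1n \sum (m_i -
#' c_i)^2}} in ears, `RRMSE = RMSE / mean(m) * 100` in percent, and
#' `bias = mean(m - c)` in ears, plus the least-squares slope/intercept of
#' predicted on manual.
#'
#' @param manual,predicted equal-length nonempty numeric vectors, or a data
#'   frame as the first argument with columns `manual_count` and
#'   `predicted_count`.
#' @return an object of class `count_evaluation`; see [glance.count_evaluation()].
#' @export
count_agreement <- function(manual, predicted = NULL) {
  if (is.data.frame(manual)) {
    predicted <- manual$predicted_count
    manual <- manual$manual_count
  }
  stopifnot(length(manual) == length(predicted), length(manual) > 0)
  keep <- !(is.na(manual) | is.na(predicted))
  manual <- as.numeric(manual[keep])
  predicted <- as.numeric(predicted[keep])
  if (length(manual) == 0L) stop("no complete manual/predicted pairs", call. = FALSE)
  m_bar <- mean(manual)
  if (m_bar <= 0) stop("mean manual count must be > 0 for RRMSE", call. = FALSE)
  ss_res <- sum((manual - predicted)^2)
  ss_tot <- sum((manual - m_bar)^2)
  rmse <- sqrt(ss_res / length(manual))
  fit <- if (length(manual) >= 2 && stats::var(manual) > 0) {
    coef(lm(predicted ~ manual))
  } else c(NA_real_, NA_real_)
  structure(list(
    pairs = tibble::tibble(manual = manual, predicted = predicted),
    n = length(manual), m_bar = m_bar,
    r2 = 1 - ss_res / ss_tot,
    rmse = rmse,
    rrmse = rmse / m_bar * 100,
    bias = mean(manual - predicted),
    intercept = unname(fit[1]), slope = unname(fit[2])
  ), class = "count_evaluation")
}

#' @export
print.count_evaluation <- function(x, ...) {
  cat(sprintf(
    "<count_evaluation: n = %d, R2 = %.3f, RMSE = %.2f ears, RRMSE = %.2f%%, bias = %.2f ears>\n",
    x$n, x$r2, x$rmse, x$rrmse, x$bias))
  invisible(x)
}

#' @rdname count_agreement
#' @param x a `count_evaluation`.
#' @param ... unused.
#' @export
tidy.count_evaluation <- function(x, ...) x$pairs

#' Count-agreement summary row
#'
#' @param x a `count_evaluation`.
#' @param ... unused.
#' @return a one-row tibble: `n`, `slope`, `intercept`, `rmse`, `r2`,
#'   `rrmse`, `bias`.
#' @export
glance.count_evaluation <- function(x, ...) {
  tibble::tibble(n = x$n, slope = x$slope, intercept = x$intercept,
                 rmse = x$rmse, r2 = x$r2, rrmse = x$rrmse, bias = x$bias)
}

#' @rdname count_agreement
#' @param object a `count_evaluation`.
#' @export
autoplot.count_evaluation <- function(object, ...) {
  rng <- range(c(object$pairs$manual, object$pairs$predicted))
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$manual, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = rng, ylim = rng) +
    ggplot2::labs(
      x = "manual count (ears)", y = "predicted count (ears)",
      title = sprintf("Count agreement (R² = %.2f, RMSE = %.2f ears)",
                      object$r2, object$rmse)) +
    ggplot2::theme_minimal()
}
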