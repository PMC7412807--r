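#' CNN architecture configuration
#'
#' The patch classifier is a fixed-depth network: five 3 x 3 same-padding
#' convolution + ReLU + 2 x 2 max-pool blocks, a flatten, and two fully
#' connected layers ending in a softmax over the four ear-count classes.
#' With 100 x 100 inputs the spatial chain is 100 - 50 - 25 - 12 - 6 - 3
#' (floor division at each pool). Channel widths and the hidden FC width
#' are configurable; `preset = "desk"` selects a slimmer network sized for
#' single-CPU experiments on synthetic patches.
#'
#' @param conv_channels integer vector of exactly 5 output channel counts.
#' @param fc_sizes integer vector of exactly 2 fully connected sizes; the
#'   last must equal 4 (the classes).
#' @param input_size integer length-3 `c(H, W, C)` input patch shape.
#' @param preset `"paper"` (16/32/64/128/256, FC 256) or `"desk"`
#'   (8/16/32/32/64, FC 64); explicit arguments override the preset.
#' @return a list of class `cnn_config`.
#' @export
cnn_config <- function(conv_channels = NULL, fc_sizes = NULL,
                       input_size = c(100L, 100L, 3L),
                       preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  if (is.null(conv_channels)) {
    conv_channels <- if (preset == "paper") c(16L, 32L, 64L, 128L, 256L)
                     else c(8L, 16L, 32L, 32L, 64L)
  }
  if (is.null(fc_sizes)) {
    fc_sizes <- if (preset == "paper") c(256L, 4L) else c(64L, 4L)
  }
  if (length(conv_channels) != 5L) {
    stop("the architecture is fixed at 5 convolution layers", call. = FALSE)
  }
  if (length(fc_sizes) != 2L || fc_sizes[2] != 4L) {
    stop("fc_sizes must have length 2 and end in 4 classes", call. = FALSE)
  }
  stopifnot(all(conv_channels >= 1), all(fc_sizes >= 1),
            length(input_size) == 3L, input_size[3] == 3L)
  # spatial sizes after each pool (floor division; odd trailing row/col drop)
  h <- input_size[1]; w <- input_size[2]
  hs <- integer(5); ws <- integer(5)
  for (l in 1:5) {
    h <- h %/% 2L; w <- w %/% 2L
    hs[l] <- h; ws[l] <- w
  }
  if (h < 1 || w < 1) stop("input too small for 5 pooling stages", call. = FALSE)
  structure(list(conv_channels = as.integer(conv_channels),
                 fc_sizes = as.integer(fc_sizes),
                 input_size = as.integer(input_size),
                 pooled_h = hs, pooled_w = ws, kernel = 3L),
            class = "cnn_config")
}

#' Training configuration
#'
#' Mini-batch training of the softmax cross-entropy loss with the Adam
#' optimizer. `epochs_mode` chooses whether `steps` counts individual
#' mini-batch iterations (`"steps"`, the default reading of a training
#' budget of 8000) or full passes over the training set (`"passes"`).
#'
#' @param steps number of training iterations (or passes).
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for batch sampling.
#' @param epochs_mode `"steps"` or `"passes"`.
#' @param log_every record loss/accuracy every this many steps.
#' @return a list of class `train_config`.
#' @export
train_config <- function(steps = 8000L, batch_size = 64L,
                         learning_rate = 1e-4, seed = 1L,
                         epochs_mode = c("steps", "passes"),
                         log_every = 50L) {
  epochs_mode <- match.arg(epochs_mode)
  stopifnot(steps >= 0, batch_size >= 1, learning_rate > 0, log_every >= 1)
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = seed,
                 epochs_mode = epochs_mode, log_every = as.integer(log_every)),
            class = "train_config")
}

#' Build a randomly initialized ear classifier
#'
#' He-normal initialization for all weights, zero biases; deterministic for
#' a fixed `seed`.
#'
#' @param cfg a [cnn_config()].
#' @param seed RNG seed for the initialization.
#' @return an object of class `ear_cnn`: architecture, weight list, and an
#'   (initially empty) training log.
#' @export
build_model <- function(cfg = cnn_config(), seed = 1L) {
  stopifnot(inherits(cfg, "cnn_config"))
  k <- cfg$kernel
  with_seed(seed, {
    weights <- list(conv = vector("list", 5L), fc = vector("list", 2L))
    cin <- cfg$input_size[3]
    for (l in 1:5) {
      cout <- cfg$conv_channels[l]
      fan_in <- k * k * cin
      weights$conv[[l]] <- list(
        W = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
        b = rep(0, cout)
      )
      cin <- cout
    }
    flat <- cfg$pooled_h[5] * cfg$pooled_w[5] * cfg$conv_channels[5]
    sizes <- c(flat, cfg$fc_sizes)
    for (m in 1:2) {
      weights$fc[[m]] <- list(
        W = matrix(rnorm(sizes[m] * sizes[m + 1], 0, sqrt(2 / sizes[m])),
                   sizes[m], sizes[m + 1]),
        b = rep(0, sizes[m + 1])
      )
    }
    structure(list(cfg = cfg, weights = weights,
                   log = tibble::tibble(step = integer(0), loss = double(0),
                                        batch_accuracy = double(0)),
                   trained_steps = 0L, seed = seed),
              class = "ear_cnn")
  })
}

#' Number of trainable parameters
#'
#' @param model an `ear_cnn`.
#' @return integer parameter count (weights plus biases).
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "ear_cnn"))
  sum(vapply(c(model$weights$conv, model$weights$fc),
             function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.ear_cnn <- function(x, ...) {
  cat(sprintf("<ear_cnn: conv %s, fc %s, %d parameters, %d training steps>\n",
              paste(x$cfg$conv_channels, collapse = "-"),
              paste(x$cfg$fc_sizes, collapse = "-"),
              n_params(x), x$trained_steps))
  invisible(x)
}

# --- internal: tensors as ((H*W*N) x C) matrices, row r = i + H*j + H*W*n ---

# stack a list of H x W x 3 patches into the network input layout, [0, 1]
patches_to_input <- function(patches) {
  X <- do.call(rbind, lapply(patches, function(p) {
    matrix(as.numeric(p), ncol = 3L)
  }))
  X / 255
}

flatten_perm <- function(h, w, C, N) {
  # permutation: F[n, i + h*j + h*w*(ch-1) + 1] = X[i + h*j + h*w*(n-1) + 1, ch]
  # built as an index into as.vector(X) (column-major (h*w*N) x C)
  hw <- h * w
  n_idx <- rep(seq_len(N), times = hw * C)
  q_idx <- rep(seq_len(hw * C), each = N)
  ch <- (q_idx - 1L) %/% hw + 1L
  pos <- (q_idx - 1L) %% hw
  pos + hw * (n_idx - 1L) + 1L + (ch - 1L) * (hw * N)
}

cnn_forward <- function(model, X, N, keep_cache = FALSE) {
  cfg <- model$cfg
  h <- cfg$input_size[1]; w <- cfg$input_size[2]
  cache <- if (keep_cache) vector("list", 5L) else NULL
  for (l in 1:5) {
    cols <- cpp_im2col(X, h, w, N, cfg$kernel, 1L)
    Z <- cols %*% model$weights$conv[[l]]$W
    cpp_add_bias(Z, model$weights$conv[[l]]$b)
    A <- pmax(Z, 0)
    mp <- cpp_maxpool(A, h, w, N)
    if (keep_cache) {
      cache[[l]] <- list(cols = cols, pre = Z, idx = mp$idx,
                         h = h, w = w, nrow_pre = nrow(A))
    }
    X <- mp$out
    h <- mp$h; w <- mp$w
  }
  C5 <- cfg$conv_channels[5]
  perm <- flatten_perm(h, w, C5, N)
  Fm <- matrix(as.vector(X)[perm], N, h * w * C5)
  G <- Fm %*% model$weights$fc[[1]]$W
  cpp_add_bias(G, model$weights$fc[[1]]$b)
  R <- pmax(G, 0)
  logits <- R %*% model$weights$fc[[2]]$W
  cpp_add_bias(logits, model$weights$fc[[2]]$b)
  list(logits = logits, cache = cache, flat = Fm, fc1_pre = G, fc1 = R,
       pooled = X, pooled_h = h, pooled_w = w, perm = perm)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

cnn_backward <- function(model, fw, X_input, y, N) {
  cfg <- model$cfg
  p <- softmax_rows(fw$logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(N), y + 1L)], 1e-12)))
  dlog <- p
  dlog[cbind(seq_len(N), y + 1L)] <- dlog[cbind(seq_len(N), y + 1L)] - 1
  dlog <- dlog / N
  grads <- list(conv = vector("list", 5L), fc = vector("list", 2L))
  grads$fc[[2]] <- list(W = crossprod(fw$fc1, dlog), b = colSums(dlog))
  dR <- dlog %*% t(model$weights$fc[[2]]$W)
  dG <- dR * (fw$fc1_pre > 0)
  grads$fc[[1]] <- list(W = crossprod(fw$flat, dG), b = colSums(dG))
  dF <- dG %*% t(model$weights$fc[[1]]$W)
  # unflatten: invert the permutation
  C5 <- cfg$conv_channels[5]
  dX <- matrix(0, fw$pooled_h * fw$pooled_w * N, C5)
  dX[fw$perm] <- as.vector(dF)
  for (l in 5:1) {
    cc <- fw$cache[[l]]
    # scatter pooled gradients back through the argmax
    dA <- matrix(0, cc$nrow_pre, ncol(dX))
    lin <- as.vector(cc$idx) +
      rep((seq_len(ncol(dX)) - 1L) * cc$nrow_pre, each = nrow(dX))
    dA[lin] <- as.vector(dX)
    dZ <- dA * (cc$pre > 0)
    grads$conv[[l]] <- list(W = crossprod(cc$cols, dZ), b = colSums(dZ))
    if (l > 1L) {
      dcols <- dZ %*% t(model$weights$conv[[l]]$W)
      cin <- cfg$conv_channels[l - 1L]
      dX <- cpp_col2im(dcols, cc$h, cc$w, N, cfg$kernel, 1L, cin)
    }
  }
  list(loss = loss, grads = grads, probs = p)
}

adam_init <- function(weights) {
  lapply(weights, function(group) {
    lapply(group, function(p) {
      list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
    })
  })
}

adam_step <- function(weights, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (g in names(weights)) {
    for (l in seq_along(weights[[g]])) {
      s <- state[[g]][[l]]
      gr <- grads[[g]][[l]]
      s$mW <- beta1 * s$mW + (1 - beta1) * gr$W
      s$vW <- beta2 * s$vW + (1 - beta2) * gr$W^2
      s$mb <- beta1 * s$mb + (1 - beta1) * gr$b
      s$vb <- beta2 * s$vb + (1 - beta2) * gr$b^2
      weights[[g]][[l]]$W <- weights[[g]][[l]]$W -
        lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
      weights[[g]][[l]]$b <- weights[[g]][[l]]$b -
        lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
      state[[g]][[l]] <- s
    }
  }
  list(weights = weights, state = state)
}

#' Train the ear classifier
#'
#' Minimizes the softmax cross-entropy by mini-batch Adam steps. Training
#' is reproducible: batches are sampled from an RNG seeded by
#' `cfg$seed` and all kernels are deterministic.
#'
#' @param model an `ear_cnn` from [build_model()].
#' @param data a `patch_dataset` from [balance_and_split()] (its `train`
#'   split is used) or a bare [patch_set()].
#' @param cfg a [train_config()].
#' @return the trained `ear_cnn`, with its `log` tibble
#'   (`step`, `loss`, `batch_accuracy`) extended.
#' @export
train_cnn <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "ear_cnn"), inherits(cfg, "train_config"))
  train <- if (inherits(data, "patch_dataset")) data$train else data
  stopifnot(inherits(train, "patch_set"))
  if (length(train) == 0L) stop("empty training set", call. = FALSE)
  present <- sort(unique(train$labels))
  if (!all(0:3 %in% present)) {
    stop("training set is missing class(es): ",
         paste(setdiff(0:3, present), collapse = ", "), call. = FALSE)
  }
  insz <- model$cfg$input_size
  if (!all(dim(train$patches[[1]])[1:2] == insz[1:2])) {
    train$patches <- lapply(train$patches, function(p) {
      p <- unclass(resize_image(rgb_image(p), insz[1], insz[2]))
      storage.mode(p) <- "integer"
      p
    })
  }
  n <- length(train)
  total_steps <- if (cfg$epochs_mode == "passes") {
    cfg$steps * max(1L, n %/% cfg$batch_size)
  } else cfg$steps
  if (total_steps == 0L) return(model)
  with_seed(cfg$seed, {
    state <- adam_init(model$weights)
    log_step <- integer(0); log_loss <- double(0); log_acc <- double(0)
    for (t in seq_len(total_steps)) {
      take <- sample.int(n, min(cfg$batch_size, n), replace = n < cfg$batch_size)
      X <- patches_to_input(train$patches[take])
      y <- train$labels[take]
      fw <- cnn_forward(model, X, length(take), keep_cache = TRUE)
      bw <- cnn_backward(model, fw, X, y, length(take))
      upd <- adam_step(model$weights, bw$grads, state, cfg$learning_rate, t)
      model$weights <- upd$weights
      state <- upd$state
      if (t %% cfg$log_every == 0L || t == total_steps || t == 1L) {
        acc <- mean(max.col(bw$probs, ties.method = "first") - 1L == y)
        log_step <- c(log_step, t)
        log_loss <- c(log_loss, bw$loss)
        log_acc <- c(log_acc, acc)
      }
    }
    model$log <- dplyr::bind_rows(
      model$log,
      tibble::tibble(step = model$trained_steps + log_step, loss = log_loss,
                     batch_accuracy = log_acc)
    )
    model$trained_steps <- model$trained_steps + total_steps
    model
  })
}

#' Classify patches
#'
#' @param object a trained `ear_cnn`.
#' @param patches a [patch_set()] or a list of patch images (resized to the
#'   model input size if needed).
#' @param batch_size forward-pass chunk size.
#' @param ... unused.
#' @return a tibble with one row per patch: `label` (argmax class, ties to
#'   the lowest index) and probabilities `p0`..`p3` (each row sums to 1).
#' @export
predict.ear_cnn <- function(object, patches, batch_size = 128L, ...) {
  plist <- if (inherits(patches, "patch_set")) patches$patches else patches
  stopifnot(is.list(plist))
  if (length(plist) == 0L) {
    return(tibble::tibble(label = integer(0), p0 = double(0), p1 = double(0),
                          p2 = double(0), p3 = double(0)))
  }
  insz <- object$cfg$input_size
  plist <- lapply(plist, function(p) {
    p <- as_rgb_image(p)
    if (!all(dim(p)[1:2] == insz[1:2])) {
      p <- resize_image(p, insz[1], insz[2])
    }
    unclass(p)
  })
  out <- vector("list", ceiling(length(plist) / batch_size))
  for (ch in seq_along(out)) {
    take <- ((ch - 1L) * batch_size + 1L):min(ch * batch_size, length(plist))
    X <- patches_to_input(plist[take])
    fw <- cnn_forward(object, X, length(take), keep_cache = FALSE)
    out[[ch]] <- softmax_rows(fw$logits)
  }
  p <- do.call(rbind, out)
  tibble::tibble(label = max.col(p, ties.method = "first") - 1L,
                 p0 = p[, 1], p1 = p[, 2], p2 = p[, 3], p3 = p[, 4])
}

#' Evaluate the classifier on a labeled test set
#'
#' @param model a trained `ear_cnn`.
#' @param test a [patch_set()] with labels.
#' @return a 4 x 4 [confusion_matrix()], rows = true class, columns =
#'   predicted class.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(test, "patch_set"), length(test) > 0L)
  pred <- predict(model, test)
  confusion_matrix(test$labels, pred$label, n_classes = 4L)
}

#' @rdname train_cnn
#' @param x an `ear_cnn`.
#' @param ... unused.
#' @export
tidy.ear_cnn <- function(x, ...) x$log

#' @rdname train_cnn
#' @export
glance.ear_cnn <- function(x, ...) {
  tibble::tibble(
    n_params = n_params(x),
    trained_steps = x$trained_steps,
    final_loss = if (nrow(x$log)) x$log$loss[nrow(x$log)] else NA_real_,
    final_batch_accuracy = if (nrow(x$log)) {
      x$log$batch_accuracy[nrow(x$log)]
    } else NA_real_
  )
}

#' @rdname train_cnn
#' @param object an `ear_cnn`.
#' @export
autoplot.ear_cnn <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "training step", y = "softmax cross-entropy",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive of the architecture and weights.
#'
#' @param model an `ear_cnn`.
#' @param path checkpoint path.
#' @return `path` (save) or the `ear_cnn` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ear_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ear_cnn"))
  model
}
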