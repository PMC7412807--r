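# Independent brute-force oracles and tiny fixture builders shared by the
# test files. These deliberately take the slow, obvious route so they stay
# independent of the package's implementations.

# --- fixtures ---------------------------------------------------------------

# image painted with a constant colour
const_image <- function(h, w, rgb) {
  rgb_image(array(rep(rgb, each = h * w), c(h, w, 3)))
}

# image with three well-separated constant colour blocks (vertical thirds)
tri_color_image <- function(h = 30, w = 30,
                            cols = list(c(220, 200, 90),   # ear yellow
                                        c(60, 140, 60),    # leaf green
                                        c(120, 95, 65))) { # soil brown
  img <- array(0, c(h, w, 3))
  thirds <- floor(seq(0, w, length.out = 4))
  for (i in 1:3) {
    idx <- (thirds[i] + 1):thirds[i + 1]
    for (ch in 1:3) img[, idx, ch] <- cols[[i]][ch]
  }
  rgb_image(img)
}

# toy patches with disjoint per-class palettes: linearly separable by colour
toy_patch <- function(klass, size = 32, noise = 4) {
  base <- list(c(40, 40, 200), c(200, 40, 40), c(40, 200, 40),
               c(200, 200, 40))[[klass + 1]]
  img <- array(rep(base, each = size * size), c(size, size, 3))
  img <- img + array(rnorm(length(img), 0, noise), dim(img))
  rgb_image(pmin(pmax(img, 0), 255))
}

toy_patch_set <- function(n_per_class, size = 32, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    patches <- list(); labels <- integer(0)
    for (k in 0:3) {
      for (i in seq_len(n_per_class)) {
        patches[[length(patches) + 1]] <- toy_patch(k, size)
        labels <- c(labels, k)
      }
    }
    patch_set(patches, labels,
              source_id = sprintf("toy_%d_%d", labels, seq_along(labels)))
  })
}

# --- oracles ----------------------------------------------------------------

# per-pixel sorted-neighbourhood median with clamped (edge-replicated) indices
oracle_median <- function(img, k) {
  img <- unclass(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  half <- k %/% 2
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        ii <- pmin(pmax(i + (-half:half), 1), h)
        jj <- pmin(pmax(j + (-half:half), 1), w)
        out[i, j, ch] <- sort(img[ii, jj, ch])[(k * k + 1) / 2]
      }
    }
  }
  out
}

# Minkowski set-shift morphology. shift_mask moves the mask so that
# out[i, j] = m[i + di, j + dj], zero outside the frame.
shift_mask <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  si <- (1:h) + di; sj <- (1:w) + dj
  ok_i <- si >= 1 & si <= h; ok_j <- sj >= 1 & sj <= w
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

se_offsets <- function(kh, kw) {
  expand.grid(di = -(kh %/% 2):(kh - 1 - kh %/% 2),
              dj = -(kw %/% 2):(kw - 1 - kw %/% 2))
}

oracle_erode <- function(m, kh, kw) {
  B <- se_offsets(kh, kw)
  shifted <- lapply(seq_len(nrow(B)),
                    function(r) shift_mask(m, B$di[r], B$dj[r]))
  out <- Reduce(function(a, b) a & b, shifted)
  out * 1L
}

oracle_dilate <- function(m, kh, kw) {
  B <- se_offsets(kh, kw)
  shifted <- lapply(seq_len(nrow(B)),
                    function(r) shift_mask(m, -B$di[r], -B$dj[r]))
  out <- Reduce(function(a, b) a | b, shifted)
  out * 1L
}

# queue-based flood fill labelling with selectable connectivity
oracle_components <- function(m, connectivity = 8) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1), dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (m[i, j] == 0 || lab[i, j] != 0) next
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (r in seq_len(nrow(nb))) {
          ii <- p[1] + nb[r, 1]; jj <- p[2] + nb[r, 2]
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
              m[ii, jj] != 0 && lab[ii, jj] == 0) {
            lab[ii, jj] <- nxt
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# nearest-centre assignment by explicit per-pixel loops
oracle_nearest_center <- function(x, centers) {
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    best <- 1L; bestd <- Inf
    for (j in seq_len(nrow(centers))) {
      d <- sum((x[i, ] - centers[j, ])^2)
      if (d < bestd) { bestd <- d; best <- j }
    }
    out[i] <- best
  }
  out
}

# loop-based classification metrics from 0-based truth/prediction vectors
oracle_class_metrics <- function(truth, pred, n_classes = 4) {
  P <- R <- F1 <- numeric(n_classes)
  for (k in seq_len(n_classes) - 1) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    P[k + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    R[k + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    F1[k + 1] <- if (P[k + 1] + R[k + 1] > 0) {
      2 * P[k + 1] * R[k + 1] / (P[k + 1] + R[k + 1])
    } else 0
  }
  tp_all <- sum(truth == pred)
  list(precision = P, recall = R, f1 = F1, macro_f1 = mean(F1),
       micro_f1 = tp_all / length(truth))
}

oracle_count_stats <- function(m, c) {
  n <- length(m)
  ss_res <- 0; for (i in 1:n) ss_res <- ss_res + (m[i] - c[i])^2
  mbar <- sum(m) / n
  ss_tot <- 0; for (i in 1:n) ss_tot <- ss_tot + (m[i] - mbar)^2
  rmse <- sqrt(ss_res / n)
  list(r2 = 1 - ss_res / ss_tot, rmse = rmse, rrmse = rmse / mbar * 100,
       bias = sum(m - c) / n)
}
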