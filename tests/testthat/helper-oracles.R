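# Independent oracles used across the suite. These deliberately share no
# code with the package: loops and direct formulas only.

# symmetric (edge-repeating) reflection of an index onto 1..n
reflect_index <- function(i, n) {
  if (i < 1) return(1 - i)
  if (i > n) return(2 * n - i + 1)
  i
}

# Double-loop local contrast: weighted mean of I^2 minus squared weighted
# mean, over the weighted mean (with the same 1e-6 stabilizer).
brute_local_contrast <- function(img, kernel) {
  h <- (nrow(kernel) - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      m1 <- 0; m2 <- 0
      for (di in -h:h) {
        for (dj in -h:h) {
          v <- img[reflect_index(i + di, nr), reflect_index(j + dj, nc)]
          w <- kernel[di + h + 1, dj + h + 1]
          m1 <- m1 + w * v
          m2 <- m2 + w * v^2
        }
      }
      out[i, j] <- max((m2 - m1^2) / (m1 + 1e-6), 0)
    }
  }
  out
}

# Explicit per-pixel confusion tally.
brute_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- truth[i, j]
      if (p == 1 && t == 1) tp <- tp + 1L
      else if (p == 1 && t == 0) fp <- fp + 1L
      else if (p == 0 && t == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Breadth-first 4-connected flood fill labeling.
brute_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i0 in seq_len(nr)) {
    for (j0 in seq_len(nc)) {
      if (mask[i0, j0] == 1L && lab[i0, j0] == 0L) {
        cur <- cur + 1L
        queue <- list(c(i0, j0))
        lab[i0, j0] <- cur
        while (length(queue)) {
          p <- queue[[1]]; queue <- queue[-1]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            ii <- p[1] + d[1]; jj <- p[2] + d[2]
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                mask[ii, jj] == 1L && lab[ii, jj] == 0L) {
              lab[ii, jj] <- cur
              queue[[length(queue) + 1]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  lab
}

# one 8-connected dilation step
dilate8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r1 <- max(1, 1 - dr); r2 <- min(nr, nr - dr)
      c1 <- max(1, 1 - dc); c2 <- min(nc, nc - dc)
      out[r1:r2, c1:c2] <- pmax(out[r1:r2, c1:c2],
                                mask[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)])
    }
  }
  out
}

# radial test image: value depends only on distance from a center
radial_image <- function(n, center, profile_fun) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rho <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  matrix(profile_fun(rho), n, n)
}

disk_mask <- function(n, center, radius) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rho <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  matrix(as.integer(rho < radius), n, n)
}

# rise-to-ridge-then-fall radial profile used by the halo recovery checks;
# like a real halo, intensity declines gently inside the boundary too, so
# the surface is strictly monotone on each side of the ridge
ridge_profile <- function(r_cell = 10, r_ridge = 14, base = 100,
                          peak = 180, fall = 25) {
  function(rho) {
    v <- ifelse(rho < r_cell, base - 2 * (r_cell - rho),
         ifelse(rho <= r_ridge,
                base + (peak - base) * (rho - r_cell) / (r_ridge - r_cell),
                pmax(peak - fall * (rho - r_ridge), base * 0.9)))
    v
  }
}
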