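# Connected-component machinery shared by the area constraint and the
# contour/halo stages. All labeling is 4-connected, matching the mask
# semantics used throughout (4-connectivity for region membership,
# 8-neighborhoods only for gradient directions).

#' Label 4-connected components of a binary mask
#'
#' Run-based two-pass labeling with union-find: runs of foreground within
#' each column are merged across adjacent columns where their row ranges
#' overlap. Background pixels get label 0; components are numbered from 1
#' in scan order.
#'
#' @param mask 0/1 integer (or logical) matrix.
#' @return Integer matrix of the same shape with component labels.
#' @export
label_components <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  # collect runs per column
  run_col <- integer(0); run_s <- integer(0); run_e <- integer(0)
  col_first <- integer(nc + 1L)  # index of first run of each column
  n_runs <- 0L
  runs_s <- vector("list", nc); runs_e <- vector("list", nc)
  for (j in seq_len(nc)) {
    v <- mask[, j]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values == 1L
    runs_s[[j]] <- starts[keep]
    runs_e[[j]] <- ends[keep]
  }
  counts <- vapply(runs_s, length, 1L)
  total <- sum(counts)
  if (total == 0L) return(labels)
  parent <- seq_len(total)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  offset <- c(0L, cumsum(counts))
  # union runs that touch across adjacent columns (same rows, 4-connected)
  for (j in seq_len(nc - 1L)) {
    na <- counts[j]; nb <- counts[j + 1L]
    if (na == 0L || nb == 0L) next
    sa <- runs_s[[j]]; ea <- runs_e[[j]]
    sb <- runs_s[[j + 1L]]; eb <- runs_e[[j + 1L]]
    a <- 1L; b <- 1L
    while (a <= na && b <= nb) {
      if (sa[a] <= eb[b] && sb[b] <= ea[a]) {
        ra <- find(offset[j] + a); rb <- find(offset[j + 1L] + b)
        if (ra != rb) parent[rb] <- ra
      }
      if (ea[a] < eb[b]) a <- a + 1L else b <- b + 1L
    }
  }
  roots <- vapply(seq_len(total), find, 1L)
  lab_of_root <- integer(total)
  next_lab <- 0L
  run_lab <- integer(total)
  for (i in seq_len(total)) {
    r <- roots[i]
    if (lab_of_root[r] == 0L) {
      next_lab <- next_lab + 1L
      lab_of_root[r] <- next_lab
    }
    run_lab[i] <- lab_of_root[r]
  }
  for (j in seq_len(nc)) {
    if (counts[j] == 0L) next
    sa <- runs_s[[j]]; ea <- runs_e[[j]]
    for (kk in seq_along(sa)) {
      labels[sa[kk]:ea[kk], j] <- run_lab[offset[j] + kk]
    }
  }
  labels
}

# out[i, j] = m[i + dr, j + dc], with `fill` outside the image.
shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 > r2 || c1 > c2) return(out)
  out[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  out
}

# (row, col) offsets: 4-neighborhood first, then diagonals.
.offsets4 <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
.offsets8 <- c(.offsets4,
               list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
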