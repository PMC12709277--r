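# Halo correction: refine the coarse contour by following directional
# intensity gradients. The halo around a phase-contrast cell rises from the
# cell boundary to a bright ridge and falls back to background; the
# correction moves the contour along that ramp and stops where the gradient
# turns negative (the ridge, i.e. the halo/boundary transition).

#' Halo-correction configuration
#'
#' @param max_iterations Iteration safeguard (>= 1); the contour can advance
#'   at most this many pixels (chessboard distance).
#' @param gradient_epsilon Intensity units; a step is taken only while the
#'   gradient along it exceeds this value. 0 requires strict ascent;
#'   slightly negative values tolerate flat, noisy stretches.
#' @param direction `"grow"` (contour moves outward from an under-covering
#'   mask, the default) or `"shrink"` (contour retreats inward from an
#'   over-covering mask); both stop at the ridge.
#' @return An object of class `halo_config`.
#' @export
halo_config <- function(max_iterations = 20L, gradient_epsilon = 0,
                        direction = c("grow", "shrink")) {
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L) {
    stop("`max_iterations` must be >= 1", call. = FALSE)
  }
  direction <- match.arg(direction)
  structure(list(max_iterations = max_iterations,
                 gradient_epsilon = gradient_epsilon,
                 direction = direction),
            class = "halo_config")
}

#' Extract the contour pixels of a binary mask
#'
#' Contour points are exactly the foreground pixels with at least one
#' background 4-neighbor; the image border counts as background.
#'
#' @param mask 0/1 integer matrix.
#' @return A list with `points`, an n x 2 integer matrix of (row, col)
#'   contour coordinates, and `mask`, a 0/1 matrix marking contour pixels.
#' @export
extract_contours <- function(mask) {
  mask <- as_mask(mask)
  bg_adj <- matrix(FALSE, nrow(mask), ncol(mask))
  for (d in .offsets4) {
    bg_adj <- bg_adj | (shift_mat(mask, d[1L], d[2L], fill = 0L) == 0L)
  }
  cm <- mask == 1L & bg_adj
  pts <- which(cm, arr.ind = TRUE)
  colnames(pts) <- c("row", "col")
  list(points = pts, mask = matrix(as.integer(cm), nrow(mask)))
}

#' Gradients in the eight compass directions at a pixel
#'
#' For each direction (top, bottom, left, right and the four diagonals) the
#' gradient is `value(point + d) - value(point)`. Out-of-bounds neighbors
#' yield `-Inf`, which reads as a negative gradient and halts growth at the
#' image border.
#'
#' @param image Numeric matrix (gray or contrast values) or [gray_image].
#' @param point Length-2 integer vector `(row, col)`, inside the image.
#' @return Named numeric vector of 8 gradients
#'   (`top`, `bottom`, `left`, `right`, `top_left`, `top_right`,
#'   `bottom_left`, `bottom_right`).
#' @export
directional_gradients <- function(image, point) {
  pix <- as_pixels(image)
  r <- point[1L]; c <- point[2L]
  if (r < 1L || r > nrow(pix) || c < 1L || c > ncol(pix)) {
    stop("`point` lies outside the image", call. = FALSE)
  }
  dirs <- list(top = c(-1L, 0L), bottom = c(1L, 0L),
               left = c(0L, -1L), right = c(0L, 1L),
               top_left = c(-1L, -1L), top_right = c(-1L, 1L),
               bottom_left = c(1L, -1L), bottom_right = c(1L, 1L))
  vapply(dirs, function(d) {
    rr <- r + d[1L]; cc <- c + d[2L]
    if (rr < 1L || rr > nrow(pix) || cc < 1L || cc > ncol(pix)) {
      return(-Inf)
    }
    pix[rr, cc] - pix[r, c]
  }, numeric(1))
}

#' Halo correction by directional gradient traversal
#'
#' Iteratively updates the mask contour on the supplied intensity surface.
#' In `"grow"` mode each background 8-neighbor of the current foreground is
#' added while the gradient from the foreground pixel to it exceeds
#' `gradient_epsilon` (the contour ascends the halo ramp); pixels whose
#' outward gradients are all at or below the epsilon stay put, so the
#' contour freezes where the gradient turns negative. In `"shrink"` mode a
#' contour pixel retreats (is removed) while the step from it toward the
#' interior, opposite one of its background neighbors, still ascends; the
#' retreat stops at the ridge where the interior step descends. In shrink
#' mode the image border is not treated as background adjacency, so
#' border-clipped regions are not eroded from the image edge.
#'
#' Iteration stops when no pixel changes or after `max_iterations` passes,
#' whichever comes first; each pass moves the contour by at most one pixel.
#'
#' @param image Numeric matrix supplying the intensity surface the gradients
#'   are read from (typically the contrast image, the raw gray image, or the
#'   Gaussian-smoothed gray image).
#' @param mask Initial 0/1 mask, same dimensions as `image`.
#' @param config A [halo_config].
#' @return A list with the corrected `mask`, the number of `iterations`
#'   performed, and `converged` (`TRUE` if the loop stopped because no pixel
#'   changed before the iteration cap).
#' @export
halo_correct <- function(image, mask, config = halo_config()) {
  pix <- as_pixels(image)
  mask <- as_mask(mask)
  if (!all(dim(pix) == dim(mask))) {
    stop("`image` and `mask` dimensions differ", call. = FALSE)
  }
  if (!inherits(config, "halo_config")) {
    stop("`config` must be a halo_config object", call. = FALSE)
  }
  eps <- config$gradient_epsilon
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    if (config$direction == "grow") {
      add <- matrix(FALSE, nrow(mask), ncol(mask))
      for (d in .offsets8) {
        # candidate q gains foreground if p = q - d is foreground and the
        # step p -> q ascends: img[q] - img[p] > eps
        fg_p <- shift_mat(mask, -d[1L], -d[2L], fill = 0L) == 1L
        val_p <- shift_mat(pix, -d[1L], -d[2L], fill = Inf)
        add <- add | (mask == 0L & fg_p & (pix - val_p > eps))
      }
      if (!any(add)) { converged <- TRUE; break }
      mask[add] <- 1L
    } else {
      # p retreats only while every step away from its background exposure
      # still ascends: for each direction d with background at p + d, the
      # inward step to p - d must have img[p - d] - img[p] > eps. One
      # non-ascending (e.g. radially descending past the ridge) direction
      # freezes the point, so the retreat stops at the ridge instead of
      # nibbling along it through flat tangential gradients.
      has_bg <- matrix(FALSE, nrow(mask), ncol(mask))
      block <- matrix(FALSE, nrow(mask), ncol(mask))
      for (d in .offsets8) {
        bg_out <- shift_mat(mask, d[1L], d[2L], fill = 1L) == 0L
        val_in <- shift_mat(pix, -d[1L], -d[2L], fill = -Inf)
        has_bg <- has_bg | bg_out
        block <- block | (bg_out & !(val_in - pix > eps))
      }
      drop <- mask == 1L & has_bg & !block
      if (!any(drop)) { converged <- TRUE; break }
      mask[drop] <- 0L
    }
    iterations <- it
  }
  list(mask = mask, iterations = iterations, converged = converged)
}
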