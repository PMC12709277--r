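#' Sampled Gaussian filter window
#'
#' Returns a square, odd-sided, isotropic Gaussian kernel renormalized to
#' sum exactly to 1. This is the filtering window used by the
#' local-contrast preprocessing; the default configuration elsewhere in the
#' package is a 3x3 window with sigma 0.8.
#'
#' @param side Odd integer >= 3, kernel side length in pixels.
#' @param sigma Positive Gaussian standard deviation in pixels.
#' @return A `filter_window`: list with `kernel` (side x side matrix summing
#'   to 1) and `side`.
#' @examples
#' w <- gaussian_window(3, 0.8)
#' sum(w$kernel)
#' @export
gaussian_window <- function(side = 3L, sigma = 0.8) {
  side <- as.integer(side)
  if (is.na(side) || side < 3L || side %% 2L == 0L) {
    stop("`side` must be an odd integer >= 3", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive number", call. = FALSE)
  }
  h <- (side - 1L) %/% 2L
  d <- seq.int(-h, h)
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  structure(list(kernel = g / sum(g), side = side), class = "filter_window")
}

#' @export
print.filter_window <- function(x, ...) {
  cat(sprintf("<filter_window> %dx%d, sum %.6f\n", x$side, x$side,
              sum(x$kernel)))
  invisible(x)
}

# 2-D correlation of `x` with a small kernel, with symmetric (reflect)
# boundary padding. Implemented as a sum of shifted submatrices: exact,
# allocation-light, and fast for the 3x3/5x5 windows used here. For the
# symmetric Gaussian windows used in this package correlation equals
# convolution.
conv2_reflect <- function(x, kernel) {
  h <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  if (h >= nr || h >= nc) stop("kernel larger than image", call. = FALSE)
  ri <- c(h:1, 1:nr, nr:(nr - h + 1L))
  ci <- c(h:1, 1:nc, nc:(nc - h + 1L))
  xp <- x[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * xp[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
    }
  }
  out
}

#' Local-contrast preprocessing
#'
#' Computes the local-contrast image
#' `C = (w * I^2 - (w * I)^2) / (w * I)`, i.e. the windowed local variance
#' divided by the windowed local mean (an index-of-dispersion contrast),
#' where `*` is 2-D convolution with the filter window `w`. A stabilizer of
#' `1e-6` is added to the denominator so that black regions do not blow up;
#' borders are handled by reflect padding; tiny negative values produced by
#' floating-point cancellation are clamped to 0.
#'
#' Cell boundaries and textured cell bodies have high local variance and so
#' map to high contrast, while a smooth background maps to values near 0
#' regardless of the local illumination level.
#'
#' @param image A [gray_image] or numeric matrix.
#' @param window A `filter_window` from [gaussian_window()].
#' @return Numeric matrix of local-contrast values, same dimensions as the
#'   input (intensity units; not bounded by the input bit depth).
#' @examples
#' img <- gray_image(matrix(100, 8, 8))
#' range(local_contrast(img, gaussian_window(3, 0.8)))  # ~0: no variance
#' @export
local_contrast <- function(image, window = gaussian_window(3L, 0.8)) {
  pix <- as_pixels(image)
  if (!inherits(window, "filter_window")) {
    stop("`window` must be created by gaussian_window()", call. = FALSE)
  }
  m1 <- conv2_reflect(pix, window$kernel)
  m2 <- conv2_reflect(pix * pix, window$kernel)
  pmax((m2 - m1 * m1) / (m1 + 1e-6), 0)
}
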