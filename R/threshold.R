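# Adaptive threshold model: histogram feature extraction (rate of rise and
# peak position of the contrast distribution), the threshold formula, the
# coarse binarization, the area-based mask constraint, and grid calibration
# of the adjustment parameter k.

#' Histogram features of a contrast image
#'
#' Container for the per-image features that drive the adaptive threshold:
#' `beta`, the rate of rise (maximum forward difference of the smoothed
#' histogram on the ascending segment toward its peak, normalized by the
#' pixel count and scaled by 1000), and `m_p`, the gray level of the
#' histogram peak.
#'
#' @param beta Non-negative rate of rise.
#' @param m_p Peak gray level (intensity units).
#' @param histogram Optional integer vector of raw counts per integer bin
#'   (bin i holds values in `[i-1, i)` of the shifted index, i.e. bin values
#'   `0, 1, ...`).
#' @param n_pixels Optional total pixel count.
#' @param value_range Optional observed `c(min, max)` of the contrast image.
#' @return An object of class `histogram_features`.
#' @export
histogram_features <- function(beta, m_p, histogram = NULL, n_pixels = NULL,
                               value_range = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("`beta` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(beta = beta, m_p = m_p, histogram = histogram,
         n_pixels = n_pixels, value_range = value_range),
    class = "histogram_features"
  )
}

#' @export
print.histogram_features <- function(x, ...) {
  cat(sprintf("<histogram_features> beta = %.4g, m_p = %.4g\n", x$beta, x$m_p))
  invisible(x)
}

# Centered moving average with the window truncated at the ends of the
# histogram. width 1 disables smoothing.
smooth_counts <- function(counts, width) {
  width <- as.integer(width)
  if (width %% 2L == 0L || width < 1L) {
    stop("`smooth_width` must be a positive odd integer", call. = FALSE)
  }
  if (width == 1L) return(as.numeric(counts))
  n <- length(counts)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, counts))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Core feature rule, operating on integer-bin counts (bin values 0, 1, ...).
# Exposed internally so the rule can be exercised on hand-built histograms.
features_from_counts <- function(counts, smooth_width = 5L) {
  n_pix <- sum(counts)
  if (n_pix == 0L) stop("empty histogram", call. = FALSE)
  sm <- smooth_counts(counts, smooth_width)
  m_p_bin <- which.max(sm) - 1L            # ties break toward the lowest bin
  first_nz <- which(counts > 0)[1L] - 1L   # first populated bin
  beta <- 0
  if (first_nz < m_p_bin) {
    seg <- sm[(first_nz + 1L):(m_p_bin + 1L)]
    beta <- max(max(diff(seg)), 0) / n_pix * 1000
  }
  list(beta = beta, m_p = m_p_bin, histogram = counts, smoothed = sm,
       n_pixels = n_pix)
}

#' Extract adaptive-threshold features from a contrast image
#'
#' Builds an integer-binned histogram of the contrast values (bin `i` counts
#' pixels with `floor(C) == i`), smooths it with a centered moving average
#' of width `smooth_width`, and derives the peak position `m_p` (bin of the
#' global smoothed maximum, ties toward the lowest bin) and the rate of rise
#' `beta` (maximum forward difference of the smoothed histogram over the
#' ascending segment from the first populated bin up to the peak, divided by
#' the pixel count and scaled by 1000). A single-valued image has no
#' ascending segment and gets `beta = 0`.
#'
#' @param contrast Numeric matrix of non-negative contrast values (or a
#'   [gray_image]).
#' @param smooth_width Odd positive integer; 1 disables smoothing.
#' @return A [histogram_features] object.
#' @export
extract_features <- function(contrast, smooth_width = 5L) {
  pix <- as_pixels(contrast)
  if (length(pix) == 0L) stop("empty image", call. = FALSE)
  vals <- floor(pmax(pix, 0))
  counts <- tabulate(as.integer(vals) + 1L, nbins = max(vals) + 1L)
  f <- features_from_counts(counts, smooth_width)
  histogram_features(beta = f$beta, m_p = f$m_p, histogram = f$histogram,
                     n_pixels = f$n_pixels, value_range = range(pix))
}

#' Adaptive threshold model parameters
#'
#' `k` is the per-dataset adjustment parameter, `l` the exponent constant
#' (2 unless explicitly overridden), and `beta_u` the maximum rate of rise
#' observed over the dataset. `beta_u = 0` is permitted only for datasets
#' whose images all have `beta = 0` (see [estimate_threshold()]).
#'
#' @param k Positive adjustment parameter.
#' @param l Exponent constant, default 2.
#' @param beta_u Non-negative dataset maximum rate of rise.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(k, beta_u, l = 2) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("`k` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(beta_u) || length(beta_u) != 1L || beta_u < 0) {
    stop("`beta_u` must be a single non-negative number", call. = FALSE)
  }
  structure(list(k = k, l = l, beta_u = beta_u), class = "threshold_params")
}

#' @export
print.threshold_params <- function(x, ...) {
  cat(sprintf("<threshold_params> k = %g, l = %g, beta_u = %g\n",
              x$k, x$l, x$beta_u))
  invisible(x)
}

#' Evaluate the adaptive threshold model
#'
#' Computes `T = Mp + k * (Mp^2 / 255) * (beta^l / beta_u - 1)`. The peak
#' position is the reference point: when the image's rate of rise matches
#' the dataset maximum (`beta^l = beta_u`) the threshold is exactly `Mp`;
#' below it the threshold is pulled under the peak toward a more
#' foreground-inclusive segmentation. When `beta = 0` the correction term
#' `beta^l / beta_u` is 0 by continuity (no division), which also covers
#' degenerate datasets with `beta_u = 0`; `beta_u <= 0` with `beta > 0` is
#' an error.
#'
#' The returned value is unclamped; callers clamp to `[0, max(C)]` before
#' thresholding (see [segment_image()]).
#'
#' @param features A [histogram_features] object.
#' @param params A [threshold_params] object.
#' @return The threshold (intensity units of the contrast image).
#' @export
estimate_threshold <- function(features, params) {
  if (!inherits(features, "histogram_features")) {
    stop("`features` must be a histogram_features object", call. = FALSE)
  }
  if (!inherits(params, "threshold_params")) {
    stop("`params` must be a threshold_params object", call. = FALSE)
  }
  beta <- features$beta
  m_p <- features$m_p
  term <- if (beta == 0) {
    0
  } else {
    if (params$beta_u <= 0) {
      stop("`beta_u` must be positive when beta > 0", call. = FALSE)
    }
    beta^params$l / params$beta_u
  }
  m_p + params$k * (m_p^2 / 255) * (term - 1)
}

#' Coarse segmentation by global thresholding
#'
#' @param contrast Numeric matrix of contrast values.
#' @param threshold Finite threshold; pixels with `C >= threshold` become
#'   foreground.
#' @return Integer 0/1 mask.
#' @export
coarse_segment <- function(contrast, threshold) {
  pix <- as_pixels(contrast)
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  m <- matrix(as.integer(pix >= threshold), nrow = nrow(pix))
  m
}

#' Area-based mask constraint
#'
#' Removes 4-connected foreground components smaller than `min_area` pixels,
#' then fills 4-connected background holes (background components not
#' touching the image border) smaller than `fill_holes_below` pixels. No
#' other pixels change; the operation is idempotent.
#'
#' @param mask 0/1 integer matrix.
#' @param min_area Non-negative component-removal floor (pixels).
#' @param fill_holes_below Non-negative hole-fill ceiling (pixels).
#' @return Constrained 0/1 integer mask.
#' @export
apply_area_constraint <- function(mask, min_area = 64, fill_holes_below = 64) {
  mask <- as_mask(mask)
  if (min_area < 0 || fill_holes_below < 0) {
    stop("area constraint values must be non-negative", call. = FALSE)
  }
  if (min_area > 1 && any(mask == 1L)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_area)
    if (length(small)) mask[lab %in% small] <- 0L
  }
  if (fill_holes_below > 1 && any(mask == 0L)) {
    bg <- 1L - mask
    lab <- label_components(bg)
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    border <- border[border > 0L]
    sizes <- tabulate(lab[lab > 0L])
    fill <- setdiff(which(sizes < fill_holes_below), border)
    if (length(fill)) mask[lab %in% fill] <- 1L
  }
  mask
}

#' Calibrate threshold parameters on an annotated image set
#'
#' `beta_u` is set to the maximum per-image rate of rise over the
#' calibration images. `k` is chosen from `k_grid` by exhaustive evaluation:
#' each candidate is plugged into the full segmentation pipeline (see
#' [segment_image()]) and the grid point maximizing the mean pixel-level F1
#' against the ground-truth masks is returned, ties broken toward the
#' smallest `k`.
#'
#' @param images List of [gray_image] objects (or matrices).
#' @param truths List of 0/1 ground-truth masks, same length and dimensions.
#' @param k_grid Non-empty numeric vector of candidate `k` values.
#' @param base A [pipeline_config] providing every other pipeline setting
#'   (window, smoothing, area constraint, halo correction, fixed peak).
#' @return A [threshold_params] with the selected `k`, `l = 2` and the
#'   estimated `beta_u`; the per-candidate mean F1 scores are attached as
#'   attribute `"scores"`.
#' @export
calibrate_threshold <- function(images, truths, k_grid,
                                base = pipeline_config()) {
  if (length(images) < 1L || length(images) != length(truths)) {
    stop("need >= 1 annotated image/truth pair of equal length", call. = FALSE)
  }
  if (length(k_grid) < 1L) stop("`k_grid` must be non-empty", call. = FALSE)
  for (i in seq_along(images)) {
    pi <- as_pixels(images[[i]])
    ti <- as_mask(truths[[i]])
    if (!all(dim(pi) == dim(ti))) {
      stop(sprintf("image/truth dimension mismatch at pair %d", i),
           call. = FALSE)
    }
  }
  window <- gaussian_window(base$window_side, base$sigma)
  betas <- vapply(images, function(im) {
    contr <- if (base$preprocess) local_contrast(im, window) else as_pixels(im)
    extract_features(contr, base$smooth_width)$beta
  }, numeric(1))
  beta_u <- max(betas)
  k_grid <- sort(k_grid)
  scores <- vapply(k_grid, function(k) {
    cfg <- base
    cfg$k <- k
    cfg$beta_u <- beta_u
    f1s <- vapply(seq_along(images), function(i) {
      res <- segment_image(images[[i]], cfg)
      m <- compute_metrics(confusion_counts(res$mask, truths[[i]]))
      m$f1
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)  # first maximum = smallest k on the sorted grid
  out <- threshold_params(k = k_grid[best], beta_u = beta_u, l = 2)
  attr(out, "scores") <- stats::setNames(scores, k_grid)
  out
}
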