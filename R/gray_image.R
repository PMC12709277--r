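#' Grayscale image container
#'
#' A `gray_image` holds a 2-D matrix of non-negative pixel intensities
#' together with its bit depth. Rows index image rows (y), columns index
#' image columns (x). Pixel values must lie in `[0, 2^bit_depth - 1]` and
#' the image must be at least 3x3 so that a 3x3 filter window fits.
#'
#' @param pixels Numeric matrix of intensities.
#' @param bit_depth Integer, 8 or 16.
#' @return An object of class `gray_image` with elements `pixels`,
#'   `height`, `width`, `bit_depth`.
#' @examples
#' img <- gray_image(matrix(100, 8, 8), bit_depth = 8)
#' img$height
#' @export
gray_image <- function(pixels, bit_depth = 8) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop("image must be at least 3x3 pixels", call. = FALSE)
  }
  if (anyNA(pixels)) stop("`pixels` contains missing values", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1) {
    stop(sprintf("pixel values must lie in [0, %d]", 2^bit_depth - 1),
         call. = FALSE)
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         bit_depth = as.integer(bit_depth)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, intensity range [%g, %g]\n",
              x$height, x$width, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept either a gray_image or a bare matrix and return the pixel matrix.
as_pixels <- function(image) {
  if (inherits(image, "gray_image")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  stop("expected a `gray_image` or a numeric matrix", call. = FALSE)
}

# Rec. 709 luminance; weights sum to 1 so equal channels map to themselves.
.lum_weights <- c(0.2126, 0.7152, 0.0722)

#' Read a grayscale image from a PNG or TIFF file
#'
#' RGB inputs are converted to luminance grayscale (Rec. 709 weights); an
#' alpha channel, if present, is dropped. The bit depth is inferred from the
#' file and pixel values are returned on the native integer scale
#' (`0..2^bit_depth - 1`), unchanged for already-gray inputs.
#'
#' @param path Path to a single-frame PNG or TIFF file.
#' @return A [gray_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    bits <- .png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(frames) > 1L) {
      stop(sprintf("'%s' is a multi-frame stack; only single frames are supported",
                   path), call. = FALSE)
    }
    arr <- frames[[1L]]
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else {
    stop(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  }
  bits <- if (bits > 8L) 16L else 8L
  scale <- 2^bits - 1
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      gray <- arr[, , 1L] * .lum_weights[1] + arr[, , 2L] * .lum_weights[2] +
        arr[, , 3L] * .lum_weights[3]
    } else {
      gray <- arr[, , 1L]  # gray + alpha
    }
  } else {
    gray <- arr
  }
  gray <- matrix(as.numeric(gray), nrow(gray), ncol(gray))
  gray_image(round(gray * scale), bit_depth = bits)
}

# PNG bit depth lives in byte 25 of the file (IHDR, after the 8-byte
# signature, 4-byte length, 4-byte type and 8 bytes of dimensions).
.png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 25L) return(8L)
  as.integer(hdr[25L])
}

#' Write an image or binary mask to a PNG or TIFF file
#'
#' Binary masks (0/1 matrices or logical matrices) are written as 8-bit
#' images with foreground 255 and background 0. Grayscale images are written
#' at their native bit depth: 8-bit images to PNG or TIFF, 16-bit images to
#' TIFF (16-bit PNG output is not supported).
#'
#' @param x A [gray_image], or a 0/1 integer or logical matrix (mask).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(x, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("cannot write '%s': directory does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (inherits(x, "gray_image")) {
    scale <- 2^x$bit_depth - 1
    norm <- x$pixels / scale
    if (ext == "png") {
      if (x$bit_depth != 8L) {
        stop("16-bit PNG output is not supported; write a TIFF instead",
             call. = FALSE)
      }
      png::writePNG(norm, path)
    } else if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(norm, path, bits.per.sample = x$bit_depth,
                      compression = "none")
    } else {
      stop(sprintf("unsupported output format '%s'", ext), call. = FALSE)
    }
  } else if (is.matrix(x)) {
    m <- (as_mask(x) == 1L) * 1.0  # foreground 255 after 8-bit scaling
    if (ext == "png") {
      png::writePNG(m, path)
    } else if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "none")
    } else {
      stop(sprintf("unsupported output format '%s'", ext), call. = FALSE)
    }
  } else {
    stop("`x` must be a gray_image or a mask matrix", call. = FALSE)
  }
  invisible(path)
}

#' Read a binary mask from an image file
#'
#' Foreground is any pixel above half intensity (masks are stored with
#' foreground 255, background 0).
#'
#' @param path Path to a mask image.
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  mid <- (2^img$bit_depth - 1) / 2
  matrix(as.integer(img$pixels > mid), nrow = img$height)
}

# Validate/coerce a mask to an integer 0/1 matrix.
as_mask <- function(mask) {
  if (is.logical(mask)) {
    storage.mode(mask) <- "integer"
    return(mask)
  }
  if (!is.matrix(mask) || !is.numeric(mask)) {
    stop("mask must be a numeric or logical matrix", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) {
    stop("mask values must be 0 or 1", call. = FALSE)
  }
  storage.mode(mask) <- "integer"
  mask
}
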