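# Seeded synthetic phase-contrast phantom generator. Scenes emulate the
# intensity structure of positive phase contrast: dark-ish textured cell
# bodies on a mid-gray background, each surrounded by a bright halo whose
# intensity rises away from the cell to a ridge just outside the true
# boundary and then decays back to background, plus a planar illumination
# tilt and Gaussian pixel noise.

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Phantom scene configuration
#'
#' Defaults describe a field of view a scientist would recognize from a 10x
#' phase-contrast image of adherent stem cells: a 256x256 frame, 12 cells of
#' radius 14-24 px, cell bodies at 75% of a background level of 120 (of
#' 255) with pixel-scale texture, a halo ridge 1.5x background peaking
#' `halo_width / 2` px outside the true boundary, a 10% illumination tilt
#' and sensor-like Gaussian noise.
#'
#' @param height,width Image dimensions in pixels.
#' @param n_cells Number of cells (overlap allowed; overlapping cells merge
#'   in the truth mask).
#' @param radius_range Length-2 vector, min/max cell radius in pixels.
#' @param cell_intensity Cell-body level as a fraction of the background.
#' @param background_level Background gray level (of 255).
#' @param halo_peak_gain Ridge height as a multiple of the background.
#' @param halo_width Pixels from the true boundary to where the halo has
#'   decayed back to background; the ridge sits at `halo_width / 2`.
#' @param ramp_inside Pixels of intensity decline inside the boundary.
#' @param illumination_tilt Maximum fractional intensity gradient across the
#'   field (planar).
#' @param noise_sigma Gaussian pixel-noise standard deviation (intensity
#'   units).
#' @param shape_irregularity Radial boundary perturbation fraction (0 gives
#'   circles).
#' @param cell_texture_sigma Pixel-scale Gaussian mottling inside cell
#'   bodies (intensity units); gives cells the within-cell contrast real
#'   phase-contrast images show.
#' @param seed Integer RNG seed; identical configs render bit-identical
#'   scenes.
#' @param cells Optional data frame with columns `row`, `col`, `radius` to
#'   place cells explicitly instead of randomly.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 256L, width = 256L, n_cells = 12L,
                           radius_range = c(14, 24), cell_intensity = 0.75,
                           background_level = 120, halo_peak_gain = 1.5,
                           halo_width = 4, ramp_inside = 2,
                           illumination_tilt = 0.1, noise_sigma = 3,
                           shape_irregularity = 0.25,
                           cell_texture_sigma = 8, seed = 1L, cells = NULL) {
  if (height < 3L || width < 3L) stop("image must be at least 3x3", call. = FALSE)
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2]) {
    stop("`radius_range` must be positive and ordered", call. = FALSE)
  }
  if (max(radius_range) > min(height, width) / 2) {
    stop("cell radius exceeds the image half-size", call. = FALSE)
  }
  if (cell_intensity <= 0 || background_level <= 0 || halo_peak_gain <= 0 ||
      halo_width <= 0) {
    stop("intensity levels and gains must be positive", call. = FALSE)
  }
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_cells = as.integer(n_cells), radius_range = radius_range,
    cell_intensity = cell_intensity, background_level = background_level,
    halo_peak_gain = halo_peak_gain, halo_width = halo_width,
    ramp_inside = ramp_inside, illumination_tilt = illumination_tilt,
    noise_sigma = noise_sigma, shape_irregularity = shape_irregularity,
    cell_texture_sigma = cell_texture_sigma, seed = as.integer(seed),
    cells = cells), class = "phantom_config")
}

# Radial intensity profile as a function of signed distance s to the true
# boundary (s < 0 inside). Piecewise cosine-tapered: cell plateau, rise to
# the ridge at s = halo_width / 2, decay to background at s = halo_width.
.halo_profile <- function(s, cfg) {
  bg <- cfg$background_level
  l_cell <- cfg$cell_intensity * bg
  l_peak <- cfg$halo_peak_gain * bg
  w_in <- cfg$ramp_inside
  ridge <- cfg$halo_width / 2
  out <- rep(bg, length(s))
  inner <- s <= -w_in
  out[inner] <- l_cell
  rise <- s > -w_in & s <= ridge
  t <- (s[rise] + w_in) / (ridge + w_in)
  out[rise] <- l_cell + (l_peak - l_cell) * (1 - cos(pi * t)) / 2
  fall <- s > ridge & s <= cfg$halo_width
  t <- (s[fall] - ridge) / (cfg$halo_width - ridge)
  out[fall] <- bg + (l_peak - bg) * (1 + cos(pi * t)) / 2
  out
}

# Draw one cell's shape: smooth radial perturbation r(theta) = r0 * a(theta)
# built from low-order harmonics (m = 2..5); the m = 2 term gives the cell
# an elliptical cast. Consumes RNG.
.draw_cell_shape <- function(irregularity) {
  m <- 2:5
  amp <- stats::rnorm(length(m))
  amp <- amp / max(sqrt(sum(amp^2)), 1e-12) * irregularity
  phase <- stats::runif(length(m), 0, 2 * pi)
  list(m = m, amp = amp, phase = phase)
}

# Boundary radius multiplier a(theta) for a cell shape, floored at 0.3 so
# the boundary never collapses through the center.
.shape_radius <- function(shape, theta) {
  a <- rep(1, length(theta))
  for (i in seq_along(shape$m)) {
    a <- a + shape$amp[i] * cos(shape$m[i] * theta + shape$phase[i])
  }
  pmax(a, 0.3)
}

#' Generate one phantom scene
#'
#' Places cells (randomly, or per `config$cells`), renders the intensity
#' field from the signed radial distance to the nearest cell boundary via
#' the rise-then-fall halo profile, adds interior texture, a planar
#' illumination tilt and Gaussian noise, and quantizes to 8-bit. The truth
#' mask is the union of cell interiors.
#'
#' @param config A [phantom_config].
#' @param render If `FALSE`, skip intensity rendering and return only the
#'   truth mask and confluency (used by target bisection).
#' @return An object of class `phantom_scene`: `image` ([gray_image]),
#'   `truth` (0/1 matrix), `true_confluency`, `cells` (data frame of
#'   centers/radii), `config`.
#' @export
generate_scene <- function(config = phantom_config(), render = TRUE) {
  if (!inherits(config, "phantom_config")) {
    stop("`config` must be a phantom_config", call. = FALSE)
  }
  h <- config$height; w <- config$width
  with_seed(config$seed, {
    if (is.null(config$cells)) {
      n <- config$n_cells
      centers_r <- stats::runif(n, 1, h)
      centers_c <- stats::runif(n, 1, w)
      radii <- stats::runif(n, config$radius_range[1], config$radius_range[2])
    } else {
      n <- nrow(config$cells)
      centers_r <- config$cells$row
      centers_c <- config$cells$col
      radii <- config$cells$radius
      if (any(radii > min(h, w) / 2)) {
        stop("cell radius exceeds the image half-size", call. = FALSE)
      }
    }
    shapes <- lapply(seq_len(n), function(i)
      .draw_cell_shape(config$shape_irregularity))

    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    s <- matrix(Inf, h, w)
    if (n > 0L) {
      for (i in seq_len(n)) {
        dy <- rows - centers_r[i]
        dx <- cols - centers_c[i]
        rho <- sqrt(dx * dx + dy * dy)
        theta <- atan2(dy, dx)
        rb <- radii[i] * .shape_radius(shapes[[i]], theta)
        s <- pmin(s, rho - rb)
      }
    }
    truth <- matrix(as.integer(s < 0), h, w)
    true_conf <- mean(truth == 1L)
    cells <- data.frame(row = centers_r, col = centers_c, radius = radii)

    if (!render) {
      return(structure(list(image = NULL, truth = truth,
                            true_confluency = true_conf, cells = cells,
                            config = config), class = "phantom_scene"))
    }

    base <- matrix(.halo_profile(as.vector(s), config), h, w)
    # planar illumination tilt in a random direction, spanning +-tilt/2
    phi <- stats::runif(1, 0, 2 * pi)
    plane <- cols * cos(phi) + rows * sin(phi)
    rngp <- range(plane)
    span <- max(rngp[2] - rngp[1], 1e-12)
    plane <- (plane - rngp[1]) / span - 0.5
    base <- base * (1 + config$illumination_tilt * plane)
    if (config$cell_texture_sigma > 0) {
      tex <- matrix(stats::rnorm(h * w, 0, config$cell_texture_sigma), h, w)
      base <- base + tex * (truth == 1L)
    }
    if (config$noise_sigma > 0) {
      base <- base + matrix(stats::rnorm(h * w, 0, config$noise_sigma), h, w)
    }
    img <- gray_image(round(pmin(pmax(base, 0), 255)), bit_depth = 8L)
    structure(list(image = img, truth = truth, true_confluency = true_conf,
                   cells = cells, config = config),
              class = "phantom_scene")
  })
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %d x %d, %d cells, true confluency %.3f\n",
              x$config$height, x$config$width, nrow(x$cells),
              x$true_confluency))
  invisible(x)
}

# Find the radius scale factor that brings true confluency within `tol` of
# `target` for a fixed layout seed; confluency is monotone in the scale
# because scaled interiors are nested. Doubles n_cells (up to 3 times) if
# the target is out of reach at the largest admissible scale.
.solve_confluency <- function(config, target, tol = 0.03) {
  base_cfg <- config
  for (attempt in 0:3) {
    cfg <- base_cfg
    cfg$n_cells <- as.integer(base_cfg$n_cells * 2^attempt)
    f_hi <- (min(cfg$height, cfg$width) / 2 - 1e-6) / max(cfg$radius_range)
    conf_at <- function(f) {
      c2 <- cfg
      c2$radius_range <- cfg$radius_range * f
      generate_scene(c2, render = FALSE)$true_confluency
    }
    lo <- 0.02; hi <- f_hi
    c_lo <- conf_at(lo); c_hi <- conf_at(hi)
    if (c_lo > target + tol) next  # even tiny cells overshoot: more cells won't help
    if (c_hi < target - tol) next  # not enough coverage: double the cells
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      c_mid <- conf_at(mid)
      if (abs(c_mid - target) <= tol / 3 || hi - lo < 1e-3) break
      if (c_mid < target) lo <- mid else hi <- mid
    }
    achieved <- conf_at(mid)
    if (abs(achieved - target) <= tol) {
      cfg$radius_range <- cfg$radius_range * mid
      return(cfg)
    }
  }
  stop(sprintf("confluency target %.3f is unreachable with this configuration",
               target), call. = FALSE)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_images` scenes (8-bit PNG image + 0/255 PNG truth mask) and a
#' manifest CSV with per-image paths, seeds and true confluency. Per-image
#' seeds are drawn deterministically from `config$seed`, so a rerun with the
#' same configuration reproduces byte-identical files. When
#' `confluency_targets` is given (one per image), cell number/radii are
#' adjusted by bisection until each scene's true confluency is within
#' 0.03 of its target.
#'
#' @param config Template [phantom_config].
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created if needed).
#' @param confluency_targets Optional numeric vector of length `n_images`.
#' @param prefix File-name prefix.
#' @return The manifest as a data frame (also written to
#'   `<out_dir>/manifest.csv`), invisibly carrying the scenes in attribute
#'   `"scenes"`.
#' @export
generate_dataset <- function(config = phantom_config(), n_images,
                             out_dir, confluency_targets = NULL,
                             prefix = "phantom") {
  if (!is.null(confluency_targets) && length(confluency_targets) != n_images) {
    stop("`confluency_targets` must have one entry per image", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L,
                                             n_images))
  rows <- vector("list", n_images)
  scenes <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg <- config
    cfg$seed <- seeds[i]
    if (!is.null(confluency_targets)) {
      cfg <- .solve_confluency(cfg, confluency_targets[i])
    }
    scene <- generate_scene(cfg)
    img_path <- file.path(out_dir, sprintf("%s_%03d.png", prefix, i))
    mask_path <- file.path(out_dir, sprintf("%s_%03d_mask.png", prefix, i))
    write_image(scene$image, img_path)
    write_image(scene$truth, mask_path)
    scenes[[i]] <- scene
    rows[[i]] <- data.frame(
      image = img_path, mask = mask_path, seed = seeds[i],
      true_confluency = scene$true_confluency,
      target = if (is.null(confluency_targets)) NA_real_
               else confluency_targets[i],
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "scenes") <- scenes
  invisible(manifest)
}
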