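test_that("contour extraction returns exactly the border-adjacent foreground", {
  expect_equal(nrow(extract_contours(matrix(0L, 6, 6))$points), 0L)

  single <- matrix(0L, 5, 5)
  single[3, 3] <- 1L
  pts <- extract_contours(single)$points
  expect_equal(unname(pts), matrix(c(3L, 3L), 1))

  # solid 5x5 square inside a large image: the 16 perimeter pixels
  m <- matrix(0L, 15, 15)
  m[6:10, 6:10] <- 1L
  got <- extract_contours(m)
  expect_equal(nrow(got$points), 16L)
  # brute-force check: foreground with a background 4-neighbor
  for (i in 1:15) {
    for (j in 1:15) {
      is_contour <- FALSE
      if (m[i, j] == 1L) {
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- i + d[1]; jj <- j + d[2]
          out <- ii < 1 || ii > 15 || jj < 1 || jj > 15
          if (out || m[ii, jj] == 0L) is_contour <- TRUE
        }
      }
      expect_equal(got$mask[i, j] == 1L, is_contour)
    }
  }

  # the image border itself counts as background: every edge pixel of an
  # all-foreground 4x4 is contour, the 4 interior pixels are not
  full <- matrix(1L, 4, 4)
  expect_equal(nrow(extract_contours(full)$points), 12L)
})

test_that("directional gradients match direct subtraction in all 8 directions", {
  flat <- matrix(5, 7, 7)
  expect_equal(unname(directional_gradients(flat, c(4, 4))), rep(0, 8))

  ramp <- matrix(rep(1:7, each = 7), 7, 7)  # v(r, c) = c
  g <- directional_gradients(ramp, c(4, 4))
  expect_equal(g[["right"]], 1)
  expect_equal(g[["left"]], -1)
  expect_equal(g[["top"]], 0)
  expect_equal(g[["bottom"]], 0)
  expect_equal(g[["top_right"]], 1)
  expect_equal(g[["bottom_left"]], -1)

  set.seed(17)
  img <- matrix(runif(81, 0, 255), 9, 9)
  g <- directional_gradients(img, c(5, 5))
  dirs <- list(top = c(-1, 0), bottom = c(1, 0), left = c(0, -1),
               right = c(0, 1), top_left = c(-1, -1), top_right = c(-1, 1),
               bottom_left = c(1, -1), bottom_right = c(1, 1))
  for (nm in names(dirs)) {
    d <- dirs[[nm]]
    expect_equal(g[[nm]], img[5 + d[1], 5 + d[2]] - img[5, 5])
  }

  # out-of-bounds neighbors read as -Inf
  g_corner <- directional_gradients(img, c(1, 1))
  expect_equal(g_corner[["top"]], -Inf)
  expect_equal(g_corner[["top_left"]], -Inf)
  expect_error(directional_gradients(img, c(0, 5)), "outside")
})

test_that("halo growth is a no-op when all outward gradients are negative", {
  # cone peaking at the center: outside the disk everything descends
  img <- radial_image(31, c(16, 16), function(rho) pmax(200 - 5 * rho, 10))
  mask <- disk_mask(31, c(16, 16), 10)
  res <- halo_correct(img, mask, halo_config(direction = "grow"))
  expect_equal(res$mask, mask)
  expect_equal(res$iterations, 0L)
  expect_true(res$converged)
})

test_that("growth recovers the ridge radius on a rise-then-fall profile", {
  n <- 41; ctr <- c(21, 21)
  img <- radial_image(n, ctr, ridge_profile(r_cell = 10, r_ridge = 14))
  mask <- disk_mask(n, ctr, 10)
  res <- halo_correct(img, mask, halo_config(max_iterations = 20,
                                             direction = "grow"))
  # oracle: the 1-D profile argmax along rays sits at rho = 14
  rho_argmax <- 14
  pts <- extract_contours(res$mask)$points
  rho <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  expect_lt(abs(mean(rho) - rho_argmax), 1)
  expect_true(res$converged)
})

test_that("shrink retreats an over-covering mask back to the ridge", {
  n <- 41; ctr <- c(21, 21)
  img <- radial_image(n, ctr, ridge_profile(r_cell = 10, r_ridge = 14))
  mask <- disk_mask(n, ctr, 18)  # well outside the ridge
  res <- halo_correct(img, mask, halo_config(max_iterations = 20,
                                             direction = "shrink"))
  pts <- extract_contours(res$mask)$points
  rho <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  expect_lt(abs(mean(rho) - 14), 1.5)
})

test_that("the iteration cap bounds growth to max_iterations rings", {
  ramp <- matrix(rep(1:21, each = 21), 21, 21)  # ascends to the right
  mask <- matrix(0L, 21, 21)
  mask[11, 3] <- 1L
  res <- halo_correct(ramp, mask, halo_config(max_iterations = 3,
                                              direction = "grow"))
  expect_equal(res$iterations, 3L)
  added <- which(res$mask == 1L & mask == 0L, arr.ind = TRUE)
  cheb <- pmax(abs(added[, 1] - 11), abs(added[, 2] - 3))
  expect_true(all(cheb <= 3))
  expect_equal(max(added[, 2] - 3), 3)  # it did advance the full 3 columns
})

test_that("growth only adds pixels, within a bounded band, and terminates", {
  set.seed(23)
  for (rep in 1:20) {
    img <- matrix(runif(400, 0, 255), 20, 20)
    mask <- matrix(rbinom(400, 1, 0.3), 20, 20)
    cap <- 5L
    res <- halo_correct(img, mask, halo_config(max_iterations = cap,
                                               direction = "grow"))
    expect_lte(res$iterations, cap)
    # growth-only: output foreground is a superset of the input
    expect_true(all(res$mask >= mask))
    # the added band is within `cap` chessboard steps of the input mask
    reach <- mask
    for (i in seq_len(cap)) reach <- dilate8(reach)
    expect_true(all(res$mask <= reach))
  }
})

test_that("a gradient-converged result is a fixed point", {
  n <- 41; ctr <- c(21, 21)
  img <- radial_image(n, ctr, ridge_profile())
  mask <- disk_mask(n, ctr, 10)
  cfg <- halo_config(max_iterations = 20, direction = "grow")
  first <- halo_correct(img, mask, cfg)
  expect_true(first$converged)
  second <- halo_correct(img, first$mask, cfg)
  expect_equal(second$mask, first$mask)
  expect_equal(second$iterations, 0L)
})

test_that("dimension mismatches are rejected", {
  expect_error(halo_correct(matrix(0, 5, 5), matrix(0L, 4, 4)), "dimensions")
})
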