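test_that("histogram features follow the stated rule on a hand-built histogram", {
  # counts over bins 0..5, smoothing disabled: peak at bin 4; the ascent
  # from the first populated bin has forward differences 20, 30, 40, so
  # beta = 40 / 240 * 1000
  counts <- c(0, 10, 30, 60, 100, 40)
  f <- halocell:::features_from_counts(counts, smooth_width = 1L)
  expect_equal(f$m_p, 4)
  expect_equal(f$beta, 40 / 240 * 1000, tolerance = 1e-12)
})

test_that("degenerate and smoothed histograms behave predictably", {
  # single-valued image: the only bin is the peak, no ascending segment
  img <- matrix(7.3, 6, 6)
  f <- extract_features(img)
  expect_equal(f$m_p, 7)
  expect_equal(f$beta, 0)

  # peak ties break toward the lowest bin
  f2 <- halocell:::features_from_counts(c(5, 9, 9, 2), smooth_width = 1L)
  expect_equal(f2$m_p, 1)

  # histogram counts sum to the pixel count
  set.seed(5)
  img <- matrix(runif(200, 0, 40), 10, 20)
  f3 <- extract_features(img)
  expect_equal(sum(f3$histogram), 200)

  # m_p lies within the observed value range (integer-bin resolution)
  for (rep in 1:10) {
    img <- matrix(runif(64, 0, 300), 8, 8)
    f4 <- extract_features(img)
    expect_gte(f4$m_p, floor(min(img)))
    expect_lte(f4$m_p, max(img))
  }
})

test_that("the threshold model has its reference point at the peak", {
  set.seed(42)
  for (rep in 1:20) {
    m_p <- runif(1, 50, 300)
    k <- runif(1, 0.2, 3)
    beta_u <- runif(1, 5, 50)
    feats <- histogram_features(beta = sqrt(beta_u), m_p = m_p)
    thr <- estimate_threshold(feats, threshold_params(k, beta_u, l = 2))
    expect_lt(abs(thr - m_p), 1e-9)
  }
})

test_that("the threshold is monotone nondecreasing in beta for k > 0", {
  params <- threshold_params(k = 0.86, beta_u = 30.99, l = 2)
  thr <- vapply(seq(0, 10, by = 0.25), function(b) {
    estimate_threshold(histogram_features(beta = b, m_p = 276), params)
  }, numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("beta = 0 yields the fully pulled-down threshold", {
  # direct substitution: T = Mp - k * Mp^2 / 255
  thr <- estimate_threshold(histogram_features(beta = 0, m_p = 209),
                            threshold_params(k = 1.68, beta_u = 27.45))
  expect_equal(thr, 209 - 1.68 * 209^2 / 255, tolerance = 1e-12)
  # degenerate dataset: beta_u = 0 is fine when beta = 0 ...
  expect_equal(
    estimate_threshold(histogram_features(beta = 0, m_p = 100),
                       threshold_params(k = 1, beta_u = 0)),
    100 - 100^2 / 255)
  # ... but not when the correction term actually divides by it
  expect_error(
    estimate_threshold(histogram_features(beta = 2, m_p = 100),
                       threshold_params(k = 1, beta_u = 0)),
    "beta_u")
})

test_that("published dataset profiles are valid parameterizations", {
  for (prof in c("c2c12", "hmscs")) {
    p <- dataset_profile(prof)
    tp <- threshold_params(p$k, p$beta_u, p$l)
    thr <- estimate_threshold(histogram_features(beta = 4, m_p = p$m_p), tp)
    expect_true(is.finite(thr))
  }
  expect_equal(dataset_profile("c2c12")[c("k", "beta_u", "m_p")],
               list(k = 0.86, beta_u = 30.99, m_p = 276))
  expect_equal(dataset_profile("hmscs")[c("k", "beta_u", "m_p")],
               list(k = 1.68, beta_u = 27.45, m_p = 209))
})

test_that("coarse segmentation respects bounds and nests across thresholds", {
  set.seed(9)
  contr <- matrix(runif(100, 0, 10), 10, 10)
  expect_true(all(coarse_segment(contr, min(contr)) == 1L))
  expect_true(all(coarse_segment(contr, max(contr) + 1) == 0L))
  thresholds <- sort(runif(5, 0, 10))
  masks <- lapply(thresholds, function(t) coarse_segment(contr, t))
  for (i in seq_len(length(masks) - 1)) {
    # higher threshold => subset of the lower-threshold mask
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  }
})

test_that("the area constraint removes, fills, and is idempotent", {
  m <- matrix(0L, 12, 12)
  m[3, 3:7] <- 1L  # 5-pixel blob
  expect_true(all(apply_area_constraint(m, min_area = 10,
                                        fill_holes_below = 0) == 0L))

  sq <- matrix(0L, 24, 24)
  sq[3:22, 3:22] <- 1L
  sq[10, 10:11] <- 0L  # 2-pixel interior hole
  filled <- apply_area_constraint(sq, min_area = 0, fill_holes_below = 8)
  expect_equal(sum(filled), 400)

  set.seed(21)
  r <- matrix(rbinom(400, 1, 0.5), 20, 20)
  expect_equal(apply_area_constraint(r, min_area = 1, fill_holes_below = 0), r)
  once <- apply_area_constraint(r, min_area = 5, fill_holes_below = 10)
  twice <- apply_area_constraint(once, min_area = 5, fill_holes_below = 10)
  expect_equal(twice, once)

  # holes touching the border are never filled
  b <- matrix(1L, 8, 8)
  b[1:4, 4] <- 0L
  expect_equal(apply_area_constraint(b, min_area = 0, fill_holes_below = 50), b)
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(13)
  for (p in c(0.2, 0.5, 0.8)) {
    m <- matrix(rbinom(15 * 11, 1, p), 15, 11)
    lab <- label_components(m)
    ref <- brute_label(m)
    # same partition: component ids may differ, memberships may not
    expect_equal(lab > 0, ref > 0)
    expect_equal(length(unique(lab[lab > 0])), length(unique(ref[ref > 0])))
    for (id in unique(ref[ref > 0])) {
      expect_equal(length(unique(lab[ref == id])), 1L)
    }
  }
  # diagonal pixels are NOT 4-connected
  d <- matrix(0L, 4, 4)
  d[1, 1] <- d[2, 2] <- 1L
  expect_equal(max(label_components(d)), 2L)
})

test_that("calibration recovers beta_u and honors a singleton grid", {
  set.seed(7)
  sc <- generate_scene(phantom_config(seed = 7, height = 96, width = 96,
                                      n_cells = 3))
  base <- pipeline_config(profile = "phantom")
  params <- calibrate_threshold(list(sc$image), list(sc$truth),
                                k_grid = 0.86, base = base)
  expect_equal(params$k, 0.86)
  contr <- local_contrast(sc$image, gaussian_window(3, 0.8))
  expect_equal(params$beta_u, extract_features(contr)$beta)
  expect_equal(params$l, 2)

  expect_error(calibrate_threshold(list(sc$image),
                                   list(sc$truth[1:10, 1:10]), 1),
               "dimension")
})
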