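test_that("posterior speed field matches per-pixel log-odds arithmetic", {
  p <- gmm_params(c(0.5, 0.5), c(20, 80), c(100, 100))
  img <- matrix(c(10, 20, 50, 50, 65, 80, 90, 95, 35), 3, 3)
  sf <- posterior_speed_field(img, p, object_components = 2)
  manual <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    lo <- log(0.5 * dnorm(img[i, j], 80, 10)) -
      log(0.5 * dnorm(img[i, j], 20, 10))
    manual[i, j] <- min(max(lo, -10), 10)
  }
  expect_equal(sf$values, manual, tolerance = 1e-12)

  # midpoint of two equal-weight equal-variance components: F = 0
  expect_equal(sf$values[matrix(c(1, 2), 1)], 0)  # pixel value 50

  # a pixel at the object mean, far from the background mean: clipped at +f_max
  expect_equal(sf$values[3, 2], 10)  # pixel value 80, exactly the object mean
  expect_gt(sf$values[1, 3], 0)      # pixel value 90, object side

  # object set must be a nonempty proper subset
  expect_error(posterior_speed_field(img, p, integer(0)),
               class = "histoseg_invalid_input")
  expect_error(posterior_speed_field(img, p, 1:2),
               class = "histoseg_invalid_input")
})

test_that("posterior speed sign separates object from background posteriors", {
  p <- gmm_params(c(0.3, 0.5, 0.2), c(20, 110, 200), c(100, 100, 100))
  img <- matrix(seq(0, 255, length.out = 64), 8, 8)
  sf <- posterior_speed_field(img, p, object_components = 3)
  post <- e_step_responsibilities(sample_set(as.numeric(img)), p)
  expect_equal(sf$values > 0, matrix(post[, 3] > post[, 1] + post[, 2], 8, 8))
})

test_that("contour initialization produces signed distance fields", {
  # full-image user mask: nonpositive everywhere, no interior zero crossing
  img <- matrix(rnorm(32 * 32, 100, 5), 32, 32)
  st <- initialize_contour(img, seg_config(init_shape = "user-mask",
                                           init_mask = matrix(1, 32, 32)))
  expect_true(all(st$phi <= 0))

  # centered square: center depth equals minus the half-side within 1 unit
  m <- matrix(0, 32, 32); m[9:24, 9:24] <- 1
  st <- initialize_contour(img, seg_config(init_shape = "user-mask",
                                           init_mask = m))
  expect_lt(abs(st$phi[16, 16] - (-8)), 1.1)
  # |grad phi| near 1 inside a narrow band around the contour (discrete
  # corners of the square overshoot; the bulk must be within 0.2)
  gm <- sqrt(((st$phi[-1, ] - st$phi[-32, ])[, -1])^2 +
             ((st$phi[, -1] - st$phi[, -32])[-1, ])^2)
  band <- abs(st$phi[-1, -1]) < 5
  expect_lt(unname(quantile(abs(gm[band] - 1), 0.9)), 0.2)

  # checkerboard: zero crossings in every 2-period window
  st <- initialize_contour(img, seg_config(init_shape = "checkerboard"))
  for (r0 in seq(1, 17, by = 16)) {
    w <- st$phi[r0:(r0 + 15), 1:16]
    expect_true(any(w < 0) && any(w >= 0))
  }

  expect_error(initialize_contour(img, seg_config(init_shape = "user-mask",
                                                  init_mask = matrix(1, 4, 4))),
               class = "histoseg_invalid_input")
})

test_that("level-set evolution: uniform expansion, CFL guard, input validation", {
  img <- matrix(0, 24, 24)
  m <- matrix(0, 24, 24); m[11:14, 11:14] <- 1
  cfg <- seg_config(init_shape = "user-mask", init_mask = m,
                    curvature_weight = 0, max_iter = 400)
  init <- initialize_contour(img, cfg)

  # uniformly positive speed grows the mask to the full image
  res <- evolve_level_set(img, matrix(1, 24, 24), init, cfg)
  expect_equal(sum(res$mask), 24 * 24)

  # CFL violation is a configuration error
  expect_error(evolve_level_set(img, matrix(10, 24, 24), init, cfg),
               class = "histoseg_config_error")
  # non-finite speed is invalid input
  bad <- matrix(1, 24, 24); bad[3, 3] <- NaN
  expect_error(evolve_level_set(img, bad, init, cfg),
               class = "histoseg_invalid_input")
})

test_that("curvature weighting smooths a speckled segmentation", {
  set.seed(8)
  ph <- generate_phantom(phantom_spec(shape = c(48, 48), noise_sigma = 0,
                                      seed = 2))
  fit <- fit_gmm_em(build_histogram(ph$image), 3)
  sf <- posterior_speed_field(ph$image, fit$params, 3)
  speckle <- sf$values + matrix(rnorm(48 * 48, 0, 4), 48, 48)
  speckle <- pmin(pmax(speckle, -10), 10) * 0.05  # CFL-safe
  cfg0 <- seg_config(curvature_weight = 0, max_iter = 200)
  cfg2 <- seg_config(curvature_weight = 2, max_iter = 200)
  init <- initialize_contour(ph$image, cfg0)
  r0 <- evolve_level_set(ph$image, speckle, init, cfg0)
  r2 <- evolve_level_set(ph$image, speckle, init, cfg2)
  expect_lt(mask_perimeter(r2$mask), mask_perimeter(r0$mask))
})

test_that("with no curvature the mask respects the sign of the speed field", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48), noise_sigma = 4,
                                      seed = 6))
  fit <- fit_gmm_em(build_histogram(ph$image), 3)
  sf <- posterior_speed_field(ph$image, fit$params, 3)
  sf$values <- sf$values * 0.05
  cfg <- seg_config(curvature_weight = 0, max_iter = 400)
  init <- initialize_contour(ph$image, cfg)
  res <- evolve_level_set(ph$image, sf, init, cfg)
  allowed <- dilate1((sf$values >= 0) * 1)  # 1-pixel numerical band
  expect_true(all(res$mask <= allowed))
})

test_that("end-to-end segmentation is accurate on phantoms and deterministic", {
  ph0 <- generate_phantom(phantom_spec(shape = c(64, 64), noise_sigma = 0,
                                       seed = 3))
  r0 <- segment(ph0$image, L = 3, object_rule = "brightest")
  expect_gte(dice_coefficient(r0$mask, ph0$truth_mask), 0.98)

  # moderate noise: 10% of the lesion-parenchyma contrast (90 units)
  ph9 <- generate_phantom(phantom_spec(shape = c(64, 64), noise_sigma = 9,
                                       seed = 3))
  r9 <- segment(ph9$image, L = 3, object_rule = "brightest")
  expect_gte(dice_coefficient(r9$mask, ph9$truth_mask), 0.90)

  # bit-identical reruns under the same seeds
  r9b <- segment(ph9$image, L = 3, object_rule = "brightest")
  expect_identical(r9$mask, r9b$mask)
  expect_identical(r9$n_iter, r9b$n_iter)

  # darkest rule targets the background component
  rd <- segment(ph0$image, L = 3, object_rule = "darkest")
  expect_gt(mean(rd$mask[ph0$label_map == 1]), 0.9)

  # constant image: upstream rejection, too few distinct values for L = 3
  expect_error(segment(matrix(5, 32, 32), L = 3),
               class = "histoseg_invalid_input")
})

test_that("3-D volumes are segmented slice-wise with congruent output", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48), noise_sigma = 5,
                                      seed = 4))
  vol <- array(c(ph$image, ph$image), dim = c(48, 48, 2))
  res <- segment(vol, L = 3, object_rule = "brightest")
  expect_identical(dim(res$mask), dim(vol))
  expect_identical(res$mask[, , 1], res$mask[, , 2])
  expect_gte(dice_coefficient(res$mask[, , 1], ph$truth_mask), 0.9)
})
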