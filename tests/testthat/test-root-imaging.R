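test_that("view stacks enforce six equal-size normalized views", {
  v <- replicate(6, matrix(runif(50), 5, 10), simplify = FALSE)
  st <- view_stack(v)
  expect_s3_class(st, "view_stack")
  expect_error(view_stack(v[1:5]), "six views")
  v2 <- v; v2[[3]] <- matrix(0.5, 6, 10)
  expect_error(view_stack(v2), "identical dimensions")
  v3 <- v; v3[[1]][1, 1] <- 1.5
  expect_error(view_stack(v3), "\\[0, 1\\]")
})

test_that("blank views stitch to a blank panorama and zero overlap concatenates", {
  v <- replicate(6, matrix(0.7, 20, 30), simplify = FALSE)
  pano <- stitch_panorama(v, overlap = 0)
  expect_equal(dim(pano), c(20, 180))
  expect_true(all(pano == 0.7))
  expect_equal(attr(pano, "offsets"), seq(0, 150, by = 30))
})

test_that("stitching recovers known view offsets within two pixels", {
  for (seed in c(11, 17, 23)) {
    sc <- render_root_scene(seed = seed)
    pano <- stitch_panorama(sc$stack)
    expect_lte(max(abs(attr(pano, "offsets") - sc$offsets)), 2)
    expect_equal(dim(pano)[1], nrow(sc$image))
  }
})

test_that("SVD denoising obeys Eckart-Young behaviour", {
  set.seed(42)
  m <- matrix(runif(30 * 20), 30, 20)
  expect_lt(max(abs(svd_denoise(m, 20) - m)), 1e-9)
  r1 <- outer(runif(30), runif(20))
  r1 <- r1 / max(r1)
  expect_lt(max(abs(svd_denoise(r1, 1) - r1)), 1e-9)
  expect_error(svd_denoise(m, 0), "positive")
  expect_error(svd_denoise(m, 21), "exceeds")

  # approximation error non-increasing in rank
  errs <- sapply(1:20, function(r) sqrt(mean((svd_denoise(m, r) - m)^2)))
  expect_true(all(diff(errs) <= 1e-12))

  # denoising a noisy low-rank image improves RMSE vs the clean truth
  clean <- matrix(0, 40, 40)
  for (k in 1:5) clean <- clean + outer(runif(40), runif(40))
  clean <- clean / max(clean)
  noisy <- pmin(pmax(clean + rnorm(1600, 0, 0.05), 0), 1)
  den <- svd_denoise(noisy, 5)
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))
})

test_that("segmentation handles blank, rendered and inverted scenes", {
  blank <- matrix(0.8, 40, 60)
  expect_false(any(segment_roots(blank)))

  sc <- render_root_scene(seed = 19, stroke_width = 3L, noise_sigma = 0.03)
  mask <- clean_top_connected(segment_roots(sc$image, sigma = 1.5))
  dice <- 2 * sum(mask & sc$mask) / (sum(mask) + sum(sc$mask))
  expect_gte(dice, 0.8)

  inv <- segment_roots(1 - sc$image, sigma = 1.5, polarity = "bright")
  expect_identical(inv, segment_roots(sc$image, sigma = 1.5, polarity = "dark"))

  bad <- sc$image; bad[5, 5] <- NA
  expect_error(segment_roots(bad), "non-finite")
})

test_that("top-connected cleaning keeps the root and drops floaters", {
  m <- matrix(FALSE, 20, 20)
  m[1:12, 9:11] <- TRUE          # root touching row 1
  expect_identical(clean_top_connected(m), m)

  speck <- m; speck[16:17, 3:4] <- TRUE
  expect_identical(clean_top_connected(speck), m)

  # output is always a subset of the input
  set.seed(10)
  for (i in 1:10) {
    rnd <- matrix(runif(400) < 0.3, 20, 20)
    out <- clean_top_connected(rnd)
    expect_true(all(!out | rnd))
  }
  expect_false(any(clean_top_connected(matrix(FALSE, 5, 5))))
})

test_that("projected area converts pixel counts by the squared coefficient", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  pa <- projected_area(m, coeff = 1)
  expect_equal(pa$pixels, 100)
  expect_equal(pa$area, 100)
  pa2 <- projected_area(m, coeff = 0.0042)
  expect_equal(pa2$area, 100 * 0.0042^2)
  expect_equal(pa2$area, 0.001764)
  expect_equal(projected_area(matrix(FALSE, 3, 3))$pixels, 0)
  expect_error(projected_area(m, coeff = 0), "positive")
})

test_that("the full pipeline recovers rendered root area within ten percent", {
  for (seed in c(11, 14, 19)) {
    sc <- render_root_scene(seed = seed, stroke_width = 3L, noise_sigma = 0.05)
    res <- segment_pipeline(sc$stack, rank = 60, sigma = 1.5)
    expect_lte(abs(res$pixels - sc$area_px) / sc$area_px, 0.10)
  }
})

test_that("growth splines reproduce cubics and their derivatives exactly", {
  t <- seq(0, 10, length.out = 12)
  y <- 2 + 0.5 * t - 0.3 * t^2 + 0.02 * t^3
  f <- fit_growth_spline(t, y, df = 6)
  expect_lt(max(abs(predict(f, t) - y)), 1e-8)
  expect_lt(max(abs(predict(f, t, deriv = 1) - (0.5 - 0.6 * t + 0.06 * t^2))), 1e-8)
  expect_error(fit_growth_spline(c(0, 1), c(1, 2)), "at least")
  expect_error(fit_growth_spline(c(0, 1, 1, 2, 3, 4, 5), rep(1, 7)), "strictly increasing")
})

test_that("noise-free logistic growth is fitted monotonically and closely", {
  sim <- simulate_growth_series(n_genotypes = 1, replicates = 1, noise_sd = 0,
                                tube_sd = 0, seed = 3)
  s <- sim$series[sim$series$tube_id == sim$series$tube_id[1], ]
  f <- fit_growth_spline(s$time, s$area, df = 6)
  expect_lt(max(abs(predict(f, s$time) - s$area)) / max(s$area), 0.01)
  grid <- seq(min(s$time), max(s$time), length.out = 200)
  expect_true(all(diff(predict(f, grid)) > -1e-6))
})

test_that("grayscale images round-trip through PNG", {
  sc <- render_root_scene(seed = 4, width = 60, height = 40)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(sc$mask, path)
  back <- read_gray_image(path)
  expect_equal(back > 0.5, sc$mask)
})
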