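test_that("site intensity is the ROI mean and respects image bounds", {
  img <- image_patch(matrix(100, 10, 10))
  expect_equal(site_intensity(img, site_roi(2, 2, 4, 4)), 100)

  m <- matrix(0, 6, 6)
  m[3:4, 3:4] <- c(10, 30, 20, 40)  # column-major: rows 3,4 x cols 3,4
  expect_equal(site_intensity(image_patch(m), site_roi(2, 2, 2, 2)), 25)
  expect_error(site_intensity(img, site_roi(8, 8, 4, 4)), "outside")
  expect_error(image_patch(matrix(300, 2, 2), bit_depth = 8), "\\[0, 255\\]")
})

test_that("histogram extremes select the reference intensity per index kind", {
  img <- image_patch(matrix(c(10, 50, 120, 200), 2, 2))
  expect_equal(histogram_extreme(img, "radiopacity"), 200)
  expect_equal(histogram_extreme(img, "translucency"), 10)
  const <- image_patch(matrix(42, 3, 3))
  expect_equal(histogram_extreme(const, "radiopacity"), 42)
  expect_equal(histogram_extreme(const, "translucency"), 42)
})

test_that("the optical index follows its defining formula", {
  expect_equal(optical_index(200, 200, "radiopacity")$value, 1)
  expect_equal(optical_index(150, 200, "radiopacity")$value, 0.75)
  expect_equal(optical_index(60, 50, "translucency")$value, 0.8)
  # radiopacity reduces to I_site / I_max, hence is scale-invariant
  for (seed in 1:10) {
    set.seed(seed)
    I_site <- runif(1, 0, 200); I_max <- runif(1, I_site, 255); c0 <- runif(1, 0.1, 3)
    expect_equal(optical_index(I_site, I_max, "radiopacity")$value, I_site / I_max)
    expect_equal(optical_index(c0 * I_site, c0 * I_max, "radiopacity")$value,
                 optical_index(I_site, I_max, "radiopacity")$value)
  }
  # translucency can go negative when I_site > 2 * I_min; flagged, kept
  neg <- optical_index(120, 50, "translucency")
  expect_lt(neg$value, 0)
  expect_true(neg$negative)
  expect_error(optical_index(10, 0, "radiopacity"), "positive")
})

test_that("extreme-pixel indices are exactly 1", {
  set.seed(4)
  img <- image_patch(matrix(runif(400, 5, 250), 20, 20))
  expect_equal(optical_index(min(img), histogram_extreme(img, "translucency"),
                             "translucency")$value, 1)
  expect_equal(optical_index(max(img), histogram_extreme(img, "radiopacity"),
                             "radiopacity")$value, 1)
})

test_that("saturation QC gates on the fraction of the representable maximum", {
  expect_true(check_saturation(image_patch(matrix(c(0, 203), 1, 2)))$pass)   # 203 < 204
  expect_false(check_saturation(image_patch(matrix(c(0, 204), 1, 2)))$pass)
  expect_false(check_saturation(image_patch(matrix(255, 2, 2)))$pass)
  expect_true(check_saturation(image_patch(matrix(100, 2, 2)))$pass)
  img16 <- image_patch(matrix(60000, 2, 2), bit_depth = 16)
  expect_false(check_saturation(img16)$pass)
  expect_true(check_saturation(img16, fraction = 0.95)$pass)
})

test_that("min-max normalization is order-preserving and affine-invariant", {
  expect_equal(normalize_indices(c(1, 2, 3)), c(0, 0.5, 1))
  v <- c(0, 0.2, 0.77, 1)
  expect_equal(normalize_indices(v), v)  # already spans [0, 1]
  set.seed(2)
  x <- rnorm(30)
  expect_equal(normalize_indices(3.2 * x - 7), normalize_indices(x))
  expect_equal(order(normalize_indices(x)), order(x))
  expect_error(normalize_indices(rep(1, 5)), "distinct")
})

test_that("correlation returns Pearson r with the adjusted R-squared", {
  x <- 1:20
  exact <- correlate(x, 2 * x + 1)
  expect_equal(exact$r, 1)
  expect_equal(exact$r_squared_adjusted, 1)
  expect_equal(correlate(x, -0.5 * x + 3)$r, -1)

  # adjusted R-squared at r = 0, n = 80: 1 - 79/78
  xs <- 1:80
  ys <- (xs - mean(xs))^2  # exactly uncorrelated with a symmetric x
  c0 <- correlate(xs, ys)
  expect_equal(c0$r, 0)
  expect_equal(c0$r_squared_adjusted, 1 - 79 / 78)

  # cross-check r, slope and intercept against the base fitting machinery
  set.seed(9)
  a <- rnorm(40); b <- 0.6 * a + rnorm(40)
  got <- correlate(a, b)
  expect_equal(got$r, cor(a, b))
  fit <- lm(b ~ a)
  expect_equal(got$slope, unname(coef(fit)[2]))
  expect_equal(got$intercept, unname(coef(fit)[1]))
  expect_equal(got$r_squared_adjusted, summary(fit)$adj.r.squared)

  expect_error(correlate(1:2, 2:3), ">= 3")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("image patches round-trip through PNG and TIFF", {
  set.seed(5)
  img <- image_patch(matrix(sample(0:255, 300, replace = TRUE), 15, 20),
                     bit_depth = 8, pixel_size = 6.25)
  for (ext in c(".png", ".tif")) {
    path <- withr::local_tempfile(fileext = ext)
    write_image_patch(img, path)
    back <- read_image_patch(path, bit_depth = 8, pixel_size = 6.25)
    expect_equal(dim(back), dim(img))
    expect_true(max(abs(back - img)) < 1)  # 8-bit quantization only
  }
  rois <- list(site_roi(0, 0, 3, 3, "a"), site_roi(5, 5, 4, 2, "b"))
  rpath <- withr::local_tempfile(fileext = ".csv")
  write_roi_table(rois, rpath)
  expect_equal(read_roi_table(rpath), rois)
})

test_that("measured ROI means track generator ground truth under noise", {
  b <- generate_micrograph(image_scenario(n_sites = 6, noise_sd = 3,
                                          vignette_model = "flat", seed = 12))
  m <- measure_sites(b$mr, b$rois, "radiopacity")
  n_px <- b$rois[[1]]$width * b$rois[[1]]$height
  target <- b$truth$radiopacity_true * 0.75 * 255
  expect_true(all(abs(m$I_site - target) < 3 * 3 / sqrt(n_px) + 1e-9))
})
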