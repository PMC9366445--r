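test_that("Von Kries grayscaling maps white to white and achromatics to v/255", {
  white <- array(255, c(3, 4, 3))
  expect_equal(von_kries_grayscale(white), matrix(1, 3, 4))

  vals <- c(0, 13, 64, 128, 200, 255)
  img <- array(rep(vals, 3), c(1, length(vals), 3))
  expect_equal(as.numeric(von_kries_grayscale(img)), vals / 255,
               tolerance = 1e-6)
})

test_that("Von Kries grayscaling matches a straight-line matrix oracle", {
  # independent re-derivation: sRGB decode -> XYZ -> HPE cone space ->
  # von Kries scaling -> XYZ -> luminance -> sRGB encode, one pixel at a time
  oracle <- function(rgb255, src_white) {
    srgb_dec <- function(v) ifelse(v <= 0.04045, v / 12.92,
                                   ((v + 0.055) / 1.055)^2.4)
    srgb_enc <- function(y) ifelse(y <= 0.0031308, 12.92 * y,
                                   1.055 * y^(1 / 2.4) - 0.055)
    M <- rbind(c(0.4124564, 0.3575761, 0.1804375),
               c(0.2126729, 0.7151522, 0.0721750),
               c(0.0193339, 0.1191920, 0.9503041))
    HPE <- rbind(c(0.40024, 0.70760, -0.08081),
                 c(-0.22630, 1.16532, 0.04570),
                 c(0, 0, 0.91822))
    d65 <- c(0.95047, 1, 1.08883)
    xyz <- M %*% srgb_dec(rgb255 / 255)
    lms <- HPE %*% xyz
    lms <- lms * (HPE %*% d65) / (HPE %*% src_white)
    srgb_enc(max(min((solve(HPE) %*% lms)[2], 1), 0))
  }
  px <- c(200, 100, 50)
  img <- array(px, c(1, 1, 3))
  expect_equal(as.numeric(von_kries_grayscale(img)),
               oracle(px, c(0.95047, 1, 1.08883)), tolerance = 1e-10)
  expect_equal(as.numeric(von_kries_grayscale(img, "D50")),
               oracle(px, c(0.96422, 1, 0.82521)), tolerance = 1e-10)
})

test_that("Von Kries grayscaling rejects malformed input", {
  expect_error(von_kries_grayscale(matrix(1, 4, 4)),
               class = "morphocontrast_format_error")
  expect_error(von_kries_grayscale(array(1, c(2, 2, 3)), "D999"),
               class = "morphocontrast_config_error")
})

test_that("exposure normalisation stretches percentiles to [0, 1]", {
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  expect_equal(normalize_exposure(img, 0, 1), img)

  expect_warning(out <- normalize_exposure(matrix(0.5, 4, 4)), "constant")
  expect_equal(out, matrix(0.5, 4, 4))

  ramp <- matrix(seq(0, 255, length.out = 400) / 255, 20, 20)
  out <- normalize_exposure(ramp, 0.01, 0.99)
  # direct percentile-computation oracle: the affine map of the two
  # quantiles, clipped to [0, 1]
  q <- quantile(ramp, c(0.01, 0.99), names = FALSE)
  expect_equal(out, pmin(pmax((ramp - q[1]) / (q[2] - q[1]), 0), 1),
               tolerance = 1e-12)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("cropping centres the specimen on a square pure-white frame", {
  img <- matrix(1, 100, 100)
  img[46:55, 41:60] <- 0.2          # dark 10 x 20 rectangle
  out <- crop_and_frame(img)
  expect_equal(dim(out), c(20, 20))
  expect_equal(sum(out < 0.98), 200)
  expect_true(all(out[out >= 0.98] == 1))

  tight <- matrix(0.3, 7, 7)
  expect_equal(crop_and_frame(tight), tight)

  expect_error(crop_and_frame(matrix(1, 5, 5)),
               class = "morphocontrast_empty_specimen_error")
})

test_that("crop bounding box equals an exhaustive pixel-scan oracle", {
  img <- matrix(1, 40, 40)
  set.seed(42)
  pts <- cbind(sample(8:30, 15, TRUE), sample(5:35, 15, TRUE))
  img[pts] <- runif(15, 0, 0.5)
  out <- crop_and_frame(img)
  rr <- range(pts[, 1]); cc <- range(pts[, 2])
  side <- max(diff(rr), diff(cc)) + 1
  expect_equal(dim(out), c(side, side))
  expect_equal(sum(out < 0.98), nrow(unique(pts)))
})

test_that("area-average step-down preserves constants, block means and image mean", {
  expect_equal(step_down(matrix(0.3, 56, 56), 28), matrix(0.3, 28, 28))
  expect_equal(step_down(rbind(c(0, 0), c(1, 1)), 1), matrix(0.5, 1, 1))

  checker <- outer(1:56, 1:56, function(i, j) (i + j) %% 2)
  expect_equal(step_down(checker, 28), matrix(0.5, 28, 28))

  img <- random_image(45, seed = 8)   # non-integer 45 -> 28 ratio
  out <- step_down(img, 28)
  expect_equal(mean(out), mean(img), tolerance = 1e-6)
  expect_equal(dim(out), c(28, 28))

  expect_error(step_down(matrix(0.5, 20, 20), 28),
               class = "morphocontrast_config_error")
})

test_that("the preparation chain is idempotent and shape-stable", {
  imgs <- generate_image_set(synthetic_config(n_groups = 2, per_group = 3,
                                              delta = 1, seed = 4))
  once <- prep_images(imgs)
  for (px in once$pixels) {
    expect_equal(dim(px), c(28, 28))
    expect_true(all(px >= 0 & px <= 1) && !anyNA(px))
  }
  twice <- prep_images(once)
  expect_equal(twice$pixels, once$pixels, tolerance = 1e-6)
})
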