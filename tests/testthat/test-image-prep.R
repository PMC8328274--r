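# Step 1: loading, grayscale conversion, smoothing, partitioning, Otsu.

test_that("PNG and TIFF round trips preserve pixel values and attach rho", {
  d <- withr::local_tempdir()
  # 8-bit all-zero grayscale PNG
  p1 <- file.path(d, "zeros.png")
  png::writePNG(matrix(0, 64, 64), p1)
  img <- load_image(p1, rho = 2)
  expect_identical(c(img$height, img$width, img$channels), c(64L, 64L, 1L))
  expect_true(all(img$pixels == 0))
  expect_equal(img$rho, 2)
  # 3-channel TIFF round trip
  arr <- array(sample(0:255, 32 * 16 * 3, replace = TRUE), c(32, 16, 3))
  p2 <- file.path(d, "rgb.tif")
  tiff::writeTIFF(arr / 255, p2, bits.per.sample = 8L)
  img2 <- load_image(p2, rho = 1.5)
  expect_equal(img2$channels, 3L)
  expect_equal(img2$pixels, arr, ignore_attr = TRUE)
  # 16-bit TIFF keeps the native integer scale
  m <- matrix(c(0, 1000, 40000, 65535), 2, 2)
  p3 <- file.path(d, "deep.tif")
  tiff::writeTIFF(rbind(cbind(m, m), cbind(m, m)) / 65535, p3, bits.per.sample = 16L)
  img3 <- load_image(p3, rho = 1)
  expect_equal(max(img3$pixels), 65535)
})

test_that("unreadable and unsupported files are rejected with informative errors", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "not_an_image.tif")
  writeLines("this is text", bad)
  expect_error(load_image(bad, rho = 1), "not_an_image")
  expect_error(load_image(file.path(d, "missing.png"), rho = 1), "not found")
  multi <- file.path(d, "stack.tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8)), multi)
  expect_error(load_image(multi, rho = 1), "multi-page|3-D")
})

test_that("grayscale conversion uses normalized Rec. 709 weights", {
  w <- grayscale_weights()
  expect_equal(sum(w), 1)
  gray <- intensity_image(matrix(7, 5, 5), 1)
  expect_identical(to_grayscale(gray)$pixels, gray$pixels)   # 1-channel identity
  arr <- array(0, c(5, 5, 3)); arr[, , ] <- 42               # (v,v,v) -> v
  expect_equal(to_grayscale(intensity_image(arr, 1))$pixels,
               matrix(42, 5, 5))
  red <- array(0, c(5, 5, 3)); red[, , 1] <- 255             # pure red
  expect_equal(to_grayscale(intensity_image(red, 1))$pixels[1, 1],
               255 * unname(w["r"]))
})

test_that("Gaussian smoothing preserves constants, mass, and matches dense convolution", {
  const <- intensity_image(matrix(13.5, 40, 40), 1)
  expect_equal(gaussian_smooth(const, 3)$pixels, const$pixels, tolerance = 1e-12)
  # single interior impulse: max stays put, total intensity conserved
  imp <- matrix(0, 41, 41); imp[21, 21] <- 100
  sm <- gaussian_smooth(intensity_image(imp, 1), 2)
  expect_equal(which(sm$pixels == max(sm$pixels)), 21L + 20L * 41L)
  expect_equal(sum(sm$pixels), 100, tolerance = 1e-8)
  # two-pixel impulse, sigma = 7, vs brute-force dense convolution oracle
  x <- matrix(0, 60, 60); x[15, 40] <- 50; x[44, 12] <- 80
  got <- gaussian_smooth(intensity_image(x, 1), 7)$pixels
  expect_equal(got, oracle_gaussian(x, 7), tolerance = 1e-10)
  expect_error(gaussian_smooth(const, -1), "sigma")
})

test_that("the FWHM interpretation rescales sigma by 2.3548", {
  set.seed(4)
  img <- intensity_image(matrix(runif(900, 0, 100), 30, 30), 1)
  a <- gaussian_smooth(img, 7, "fwhm")$pixels
  b <- gaussian_smooth(img, 7 / (2 * sqrt(2 * log(2))), "sd")$pixels
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("smoothing is shift-equivariant away from the boundary", {
  set.seed(9)
  base <- matrix(runif(80 * 80, 0, 255), 80, 80)
  shifted <- matrix(0, 80, 80)
  shifted[6:80, ] <- base[1:75, ]  # translate 5 rows down
  a <- gaussian_smooth(intensity_image(base, 1), 3)$pixels
  b <- gaussian_smooth(intensity_image(shifted, 1), 3)$pixels
  expect_equal(b[31:60, 21:60], a[26:55, 21:60], tolerance = 1e-10)
})

test_that("center partition follows the floor-based 3x3 grid", {
  m9 <- matrix(seq_len(81), 9, 9)
  cp <- center_partition(intensity_image(m9, 1))
  expect_equal(cp$pixels, m9[4:6, 4:6])           # 0-based rows/cols 3..5
  m10 <- matrix(seq_len(100), 10, 10)
  cp10 <- center_partition(intensity_image(m10, 1))
  expect_equal(cp10$pixels, m10[4:6, 4:6])        # floor convention
  big <- center_partition(intensity_image(matrix(0, 300, 600), 1))
  expect_identical(c(big$height, big$width), c(100L, 200L))
  expect_error(center_partition(intensity_image(matrix(0, 2, 5), 1)), "3x3")
})

test_that("center partition area stays within the floor/ceiling bounds", {
  for (h in c(3, 7, 10, 11, 100, 301)) for (w in c(3, 8, 13, 99)) {
    cp <- center_partition(intensity_image(matrix(0, h, w), 1))
    a <- cp$height * cp$width
    expect_gte(a, floor(h / 3) * floor(w / 3))
    expect_lte(a, ceiling(h / 3) * ceiling(w / 3))
  }
})

test_that("Otsu separates a bimodal region and rejects constant regions", {
  x <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t <- otsu_threshold(intensity_image(x, 1))
  expect_gt(t, 10); expect_lt(t, 200)
  expect_equal(sum(x > t), 50)
  expect_error(otsu_threshold(intensity_image(matrix(5, 10, 10), 1)), "degenerate")
})

test_that("Otsu equals the exhaustive intra-class-variance minimizer on random 8-bit regions", {
  set.seed(101)
  for (i in 1:25) {
    x <- matrix(sample(0:255, 120, replace = TRUE,
                       prob = runif(256)^2), 12, 10)
    if (length(unique(as.vector(x))) < 2) next
    expect_equal(otsu_threshold(intensity_image(x, 1)), oracle_otsu_8bit(x))
  }
})

test_that("binarize uses the strict > convention and is monotone in the threshold", {
  z <- intensity_image(matrix(0, 8, 8), 1)
  expect_false(any(binarize(z, 1)$mask))
  eq <- intensity_image(matrix(50, 8, 8), 1)
  expect_false(any(binarize(eq, 50)$mask))         # boundary: = is background
  set.seed(2)
  img <- intensity_image(matrix(sample(0:255, 400, TRUE), 20, 20), 1)
  prev <- binarize(img, -1)$mask
  for (t in c(0, 50, 128, 254)) {
    cur <- binarize(img, t)$mask
    expect_true(all(prev | !cur))                  # raising t never adds pixels
    prev <- cur
  }
})
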