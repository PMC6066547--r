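test_that("luminance and contrast follow the weighted-intensity definition", {
  white <- image_rgb(array(255, c(4, 4, 3)))
  expect_equal(weighted_intensity_stats(white),
               c(luminance = 255, global_contrast = 0))

  green <- array(0, c(4, 4, 3)); green[, , 2] <- 255
  expect_equal(weighted_intensity_stats(image_rgb(green))[["luminance"]],
               0.587 * 255)

  two_tone <- matrix(c(rep(0, 8), rep(255, 8)), 4, 4)
  ws <- weighted_intensity_stats(image_rgb(two_tone))
  expect_equal(unname(ws), c(127.5, 127.5))
})

test_that("gradient energy matches forward-difference formulas and oracle", {
  const <- image_rgb(array(42, c(5, 7, 3)))
  expect_equal(gradient_energy(const, "both"), 0)

  # horizontal ramp, step s = 10, on a 5 x 6 grid
  ramp <- matrix(rep(seq(0, 50, by = 10), each = 5), 5, 6)
  rimg <- image_rgb(ramp)
  expect_equal(gradient_energy(rimg, "horizontal"), 5 * 5 * 100)
  expect_equal(gradient_energy(rimg, "vertical"), 0)

  for (seed in 1:5) {
    img <- rand_image(3, 3, 200 + seed)
    y <- luma_oracle(img)
    for (ax in c("horizontal", "vertical", "both")) {
      expect_equal(gradient_energy(img, ax), gradient_brute(y, ax),
                   tolerance = 1e-12)
    }
  }
})

test_that("spectral band energies follow the radial mask definition", {
  const <- image_rgb(array(10, c(6, 4, 3)))
  expect_equal(spectral_band_energy(const, "low"), 10 * 6 * 4)
  expect_equal(spectral_band_energy(const, "high"), 0)

  # period-2 checkerboard: all energy at the Nyquist corner (radius sqrt(2))
  cb <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 100, 50))
  cbi <- image_rgb(cb)
  expect_equal(spectral_band_energy(cbi, "high"),
               abs(sum(cb * outer(1:8, 1:8, function(i, j) (-1)^(i + j)))))
  # low band holds only the DC term for the checkerboard
  expect_equal(spectral_band_energy(cbi, "low"), sum(cb))

  for (seed in 1:4) {
    img <- rand_image(8, 8, 300 + seed)
    y <- luma_oracle(img)
    expect_equal(spectral_band_energy(img, "low"),
                 band_energy_brute(y, "low"), tolerance = 1e-9)
    expect_equal(spectral_band_energy(img, "high"),
                 band_energy_brute(y, "high"), tolerance = 1e-9)
  }
})

test_that("color statistics follow the YIQ / max-min definitions", {
  gray <- rand_gray_image(5, 5, 31)
  cs <- color_stats(gray)
  expect_equal(unname(cs["colorfulness"]), 0, tolerance = 1e-9)
  expect_equal(unname(cs["saturation"]), 0)

  red <- array(0, c(3, 3, 3)); red[, , 1] <- 255
  expect_equal(unname(color_stats(image_rgb(red))["saturation"]), 255)

  px <- image_rgb(array(rep(c(100, 50, 200), each = 4), c(2, 2, 3)))
  expect_equal(unname(color_stats(px)["colorfulness"]),
               4 * chroma_brute(100, 50, 200), tolerance = 1e-9)

  black <- image_rgb(array(0, c(3, 3, 3)))
  expect_equal(unname(color_stats(black)["saturation"]), 0)
})

test_that("local contrast averages within-block population SDs", {
  const <- image_rgb(array(9, c(8, 8, 3)))
  expect_equal(local_contrast(const, 4), 0)

  # constant within each 4x4 tile, varying across tiles
  tiles <- kronecker(matrix(c(10, 200, 60, 130), 2, 2), matrix(1, 4, 4))
  expect_equal(local_contrast(image_rgb(tiles), 4), 0)

  for (seed in 1:4) {
    img <- rand_image(8, 8, 400 + seed)
    expect_equal(local_contrast(img, 4),
                 local_contrast_brute(luma_oracle(img), 4),
                 tolerance = 1e-12)
  }
  expect_error(local_contrast(const, 1), "tile")
  expect_error(local_contrast(const, 20), "tile")
})

test_that("assembled feature vectors are deterministic and consistent", {
  gray <- image_rgb(array(120, c(8, 8, 3)))
  f <- extract_extended(gray)
  expect_equal(unname(f[c("gradient", "global_contrast", "colorfulness",
                          "saturation", "local_contrast",
                          "high_frequencies")]),
               rep(0, 6), tolerance = 1e-9)

  img <- rand_image(10, 10, 55)
  expect_identical(extract_extended(img), extract_extended(img))
  f2 <- extract_extended(img)
  expect_equal(f2[["gradient"]],
               f2[["horizontal_gradient"]] + f2[["vertical_gradient"]])
  expect_length(f2, 13)
})

test_that("scale and transposition properties hold", {
  img <- rand_image(8, 8, 66)
  px <- unclass(img)
  for (cc in c(0.5, 0.25)) {
    scaled <- image_rgb(px * cc)
    expect_equal(gradient_energy(scaled), cc^2 * gradient_energy(img),
                 tolerance = 1e-9)
    expect_equal(spectral_band_energy(scaled, "low"),
                 cc * spectral_band_energy(img, "low"), tolerance = 1e-9)
  }
  tr <- image_rgb(aperm(px, c(2, 1, 3)))
  expect_equal(gradient_energy(tr, "horizontal"),
               gradient_energy(img, "vertical"))
  expect_equal(gradient_energy(tr, "vertical"),
               gradient_energy(img, "horizontal"))
  expect_equal(spectral_band_energy(tr, "low"),
               spectral_band_energy(img, "low"), tolerance = 1e-9)
  expect_equal(unname(color_stats(tr)), unname(color_stats(img)),
               tolerance = 1e-9)
})

test_that("feature ratios are invariant to the sum-vs-mean convention", {
  # for same-size images, sum = npix * mean, so ratios cancel the npix
  a <- rand_image(8, 8, 71); b <- rand_image(8, 8, 72)
  fa <- extract_features(a); fb <- extract_features(b)
  npix <- 64
  expect_equal(fa[["colorfulness"]] / fb[["colorfulness"]],
               (fa[["colorfulness"]] / npix) / (fb[["colorfulness"]] / npix))
})

test_that("greedy de-correlation picks one member of each duplicated pair", {
  set.seed(77)
  base <- matrix(rnorm(40 * 6), 40, 6)
  X <- cbind(base, base)  # features 7-12 exact copies of 1-6
  colnames(X) <- c(paste0("f", 1:6), paste0("g", 1:6))
  sel <- select_least_correlated(X, 6)
  expect_length(sel$selected, 6)
  for (i in 1:6) {
    expect_equal(sum(sel$selected %in% c(paste0("f", i), paste0("g", i))), 1)
  }

  allsel <- select_least_correlated(X[, 1:6], 6)
  expect_setequal(allsel$selected, paste0("f", 1:6))

  neg <- cbind(a = rnorm(30))
  neg <- cbind(neg, b = -neg[, "a"])
  one <- select_least_correlated(neg, 1)
  expect_length(one$selected, 1)

  Xc <- cbind(X[, 1:3], const = rep(2, 40))
  flagged <- select_least_correlated(Xc, 2)
  expect_true("const" %in% flagged$flagged_constant)
  expect_false("const" %in% flagged$selected)
})
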