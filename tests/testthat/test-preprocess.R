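# Image enhancement stages against closed forms and brute-force oracles.

test_that("grayscale conversion uses the luminance weights", {
  rgb <- array(0, c(4, 5, 3))
  rgb[, , 1] <- 90; rgb[, , 2] <- 90; rgb[, , 3] <- 90
  expect_true(all(to_grayscale(rgb) == 90))
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 255
  expect_true(all(to_grayscale(red) == 76))  # round(0.299 * 255)
  g <- matrix(17, 3, 3)
  expect_identical(to_grayscale(g), g)
  expect_error(to_grayscale(array(0, c(2, 2, 2))), "channel")
})

test_that("gamma correction matches its closed form and fixes endpoints", {
  ramp <- matrix(as.numeric(0:255), 1)
  for (g in c(0.5, 1, 1.2, 2)) {
    expect_identical(gamma_correct(ramp, g),
                     pmin(pmax(floor((ramp / 255)^g * 255 + 0.5), 0), 255))
  }
  expect_identical(gamma_correct(ramp, 1), ramp)
  expect_identical(gamma_correct(matrix(c(0, 255), 1), 3.7), matrix(c(0, 255), 1))
  expect_identical(gamma_correct(matrix(128, 1), 2)[1], 64)  # 128^2/255 = 64.25
  expect_error(gamma_correct(ramp, 0), "positive")
  expect_error(gamma_correct(ramp, -1), "positive")
})

test_that("gamma correction is monotone and invertible up to rounding", {
  ramp <- matrix(as.numeric(0:255), 1)
  for (g in c(0.4, 1.2, 2.5)) {
    expect_true(all(diff(gamma_correct(ramp, g)[1, ]) >= 0))
  }
  # round-trip inversion holds to one intensity unit for moderate gammas;
  # strong gammas collapse low intensities to 0, which no inverse recovers
  for (g in c(0.8, 1.2, 1.25)) {
    back <- gamma_correct(gamma_correct(ramp, g), 1 / g)
    expect_lte(max(abs(back - ramp)), 1)
  }
})

test_that("bilateral filter matches the brute-force reference", {
  expect_identical(bilateral_filter(matrix(140, 10, 10)), matrix(140, 10, 10))
  set.seed(21)
  for (i in 1:5) {
    patch <- random_int_image(16, 16)
    expect_lte(max(abs(bilateral_filter(patch, 9, 75, 75) -
                         bf_bilateral(patch, 9, 75, 75))), 1)
  }
  expect_error(bilateral_filter(matrix(1, 4, 4), sigma_range = 0), "positive")
})

test_that("bilateral filter preserves step edges and reduces to Gaussian", {
  # ideal step edge, range sigma far below the step height: no pixel
  # crosses the midpoint
  step <- cbind(matrix(20, 12, 6), matrix(220, 12, 6))
  out <- bilateral_filter(step, 9, sigma_range = 10, sigma_spatial = 75)
  expect_true(all(out[, 1:6] < 120) && all(out[, 7:12] > 120))
  # single impulse on a flat field with a huge range sigma behaves like a
  # plain Gaussian blur (all range weights ~1): compare to the brute-force
  # formula evaluated with the range kernel removed
  imp <- matrix(100, 9, 9); imp[5, 5] <- 110
  out2 <- bilateral_filter(imp, 9, sigma_range = 1e6, sigma_spatial = 2)
  gauss <- bf_bilateral(imp, 9, 1e12, 2)
  expect_lte(max(abs(out2 - gauss)), 1)
})

test_that("adaptive threshold matches the brute-force reference exactly", {
  set.seed(22)
  for (i in 1:5) {
    patch <- random_int_image(32, 32)
    expect_identical(adaptive_threshold(patch, 11, 5),
                     bf_adaptive(patch, 11, 5, inverse = TRUE))
    expect_identical(adaptive_threshold(patch, 11, 5, polarity = "direct"),
                     bf_adaptive(patch, 11, 5, inverse = FALSE))
  }
  expect_error(adaptive_threshold(patch, 10, 5), "odd")
})

test_that("adaptive threshold handles flat, ramp and polarity cases", {
  expect_true(all(adaptive_threshold(matrix(80, 20, 20), 11, 3) == 0))
  # per-column ramp with a full-width window and C = 0: exactly the
  # lower-intensity half becomes foreground under inverse polarity
  ramp <- matrix(rep(seq(0, 255, length.out = 33), each = 5), 5, 33)
  ramp <- round(ramp)
  out <- adaptive_threshold(ramp, 65, 0)
  expect_identical(out, bf_adaptive(ramp, 65, 0, TRUE))
  expect_true(all(out[, 1:16] == 255) && all(out[, 17:33] == 0))
  # dark digits on a light field: strokes become foreground
  field <- matrix(220, 30, 30)
  field[10:20, 10:12] <- 40
  out2 <- adaptive_threshold(field, 15, 5)
  expect_true(all(out2[10:20, 10:12] == 255))
})

test_that("the enhancement chain is binary, deterministic and sane", {
  expect_true(all(enhance(matrix(0, 40, 40)) == 0))
  sc <- render_scene(list(sbp = 120, dbp = 80, hr = 72), noise_sd = 0)
  b1 <- enhance(sc$image)
  expect_true(all(b1 %in% c(0, 255)))
  expect_identical(b1, enhance(sc$image))
  # foreground inside the ground-truth BP box covers the digit strokes:
  # every rendered ink pixel is foreground after enhancement
  ink <- sc$image == sc$layout$shades$ink
  expect_gte(mean(b1[ink] == 255), 0.98)
})

test_that("enhancement parameters are validated", {
  expect_error(enhance_params(block_size = 10), "odd")
  expect_error(enhance_params(gamma = -2), "positive")
  expect_error(enhance_params(sigma_range = 0), "positive")
})
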