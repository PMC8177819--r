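# Frame cropping, fixed-size scaling, border trimming and the SBP/DBP split.

test_that("extract_frame follows the half-open box convention", {
  img <- blob_image(40, 60, list(bbox(10, 5, 20, 12)))
  expect_identical(extract_frame(img, bbox(0, 0, 60, 40)), img)
  px <- extract_frame(img, bbox(10, 5, 1, 1))
  expect_identical(dim(px), c(1L, 1L))
  expect_identical(px[1, 1], 255)
  crop <- extract_frame(img, bbox(8, 3, 30, 20))
  expect_identical(extract_frame(crop, bbox(0, 0, 30, 20)), crop)
  expect_error(extract_frame(img, bbox(50, 30, 20, 20)), "extent")
})

test_that("scale_to_fixed produces exact-size binary output", {
  sq <- blob_image(50, 50, list(bbox(10, 10, 30, 30)))
  same <- scale_to_fixed(sq, 50, 50)
  expect_identical(same, sq)
  up <- scale_to_fixed(sq, 100, 100)
  expect_identical(dim(up), c(100L, 100L))
  ct <- find_contours(up)
  expect_lte(abs(ct$w[1] - 60), 2)
  expect_lte(abs(ct$h[1] - 60), 2)
  checker <- matrix(c(0, 255), 64, 64)
  down <- scale_to_fixed(checker, 16, 16)
  expect_identical(dim(down), c(16L, 16L))
  expect_true(all(down %in% c(0, 255)))
  expect_error(scale_to_fixed(sq, 0, 10), "positive")
})

test_that("trim_border removes symmetric strips", {
  f <- matrix(0, 100, 100)
  expect_identical(trim_border(f, 0, 0), f)
  expect_identical(dim(trim_border(f, 5, 8)), c(90L, 84L))
  inner <- blob_image(100, 100, list(bbox(20, 20, 40, 40)))
  expect_identical(sum(trim_border(inner, 10, 10) > 0), sum(inner > 0))
  expect_error(trim_border(f, 50, 0), "at least one")
})

test_that("split_bp_frame divides at half height, bottom keeps the extra row", {
  f <- matrix(0, 160, 100)
  f[1:80, 1] <- 255    # marker in the top half
  halves <- split_bp_frame(f, 100, 80)
  expect_identical(dim(halves$sbp), c(80L, 100L))
  expect_identical(dim(halves$dbp), c(80L, 100L))
  odd <- matrix(0, 161, 100)
  odd[81, 50] <- 255   # row 81 belongs to the bottom half (floor convention)
  h2 <- split_bp_frame(odd, 100, 80)
  expect_true(all(h2$sbp == 0))
  expect_gt(sum(h2$dbp), 0)
  expect_error(split_bp_frame(matrix(0, 1, 10)), "height")
})

test_that("splitting then re-concatenating reproduces the frame", {
  set.seed(41)
  f <- matrix(sample(c(0, 255), 160 * 100, replace = TRUE), 160, 100)
  cut <- floor(nrow(f) / 2)
  top <- f[1:cut, ]; bottom <- f[(cut + 1):nrow(f), ]
  expect_identical(rbind(top, bottom), f)
})

test_that("normalized pipeline frames are 180x80 binary and idempotent", {
  sc <- bpocr:::synth_scene(synthetic_spec(1, c(OK = 1), seed = 8))
  bin <- enhance(sc$image)
  fp <- localize_frames(bin)
  fr <- normalize_frames(bin, fp)
  for (f in fr[!vapply(fr, is.null, logical(1))]) {
    expect_identical(dim(f), c(80L, 180L))
    expect_true(all(f %in% c(0, 255)))
    # a frame already at target size passes through scaling unchanged
    expect_identical(scale_to_fixed(f, 180, 80), f)
  }
})

test_that("the systolic half carries the systolic glyphs only", {
  # clean scene of (120, 80, 72) on the default layout, frames cut at the
  # ground-truth boxes: the SBP frame must show the leading "1" (left
  # region) while the DBP frame, right-aligned "80", stays empty there
  sc <- render_scene(list(sbp = 120, dbp = 80, hr = 72), noise_sd = 0)
  bin <- enhance(sc$image)
  fp <- structure(list(bp = sc$lcd_box, hr = sc$hr_box), class = "frame_pair")
  fr <- normalize_frames(bin, fp)
  expect_gt(sum(fr$sbp[, 1:65]), 0)
  expect_identical(sum(fr$dbp[, 1:50]), 0)
  # both carry glyphs on the right
  expect_gt(sum(fr$sbp[, 100:180]), 0)
  expect_gt(sum(fr$dbp[, 100:180]), 0)
})
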