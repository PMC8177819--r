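# Contour extraction, aspect-ratio filtering and frame selection.

test_that("find_contours returns tight boxes in size order", {
  expect_identical(nrow(find_contours(matrix(0, 20, 20))), 0L)
  one <- blob_image(30, 40, list(bbox(5, 5, 20, 10)))
  ct <- find_contours(one)
  expect_identical(nrow(ct), 1L)
  expect_identical(ct[1, c("x", "y", "w", "h")],
                   data.frame(x = 5L, y = 5L, w = 20L, h = 10L))
  two <- blob_image(40, 60, list(bbox(2, 2, 10, 5), bbox(20, 10, 30, 20)))
  ct2 <- find_contours(two)
  expect_identical(nrow(ct2), 2L)
  expect_identical(ct2$w[1], 30L)  # larger area first
  expect_true(all(diff(ct2$area) <= 0))
})

test_that("components are 8-connected", {
  img <- matrix(0, 10, 10)
  img[3, 3] <- 255; img[4, 4] <- 255  # diagonal touch: one component
  expect_identical(nrow(find_contours(img)), 1L)
  img2 <- matrix(0, 10, 10)
  img2[3, 3] <- 255; img2[3, 6] <- 255
  expect_identical(nrow(find_contours(img2)), 2L)
})

test_that("aspect_ratio follows width over height", {
  expect_identical(aspect_ratio(bbox(0, 0, 100, 50)), 2)
  expect_identical(aspect_ratio(bbox(0, 0, 50, 50)), 1)
  expect_equal(aspect_ratio(bbox(0, 0, 137, 146)), 0.938, tolerance = 1e-3)
})

test_that("localize_frames recovers the BP frame on clean scenes", {
  set.seed(31)
  for (i in 1:5) {
    sc <- bpocr:::synth_scene(synthetic_spec(1, c(OK = 1), seed = i))
    fp <- localize_frames(enhance(sc$image))
    expect_false(is.null(fp))
    expect_gte(box_iou(fp$bp, sc$lcd_box), 0.8)
  }
})

test_that("localize_frames handles missing candidates", {
  expect_null(localize_frames(matrix(0, 60, 80)))
  # one LCD-like square blob, no HR blob
  sq <- blob_image(100, 100, list(bbox(30, 30, 40, 40)))
  fp <- localize_frames(sq, localize_params(bp_area = c(0.01, 0.9)))
  expect_s3_class(fp, "frame_pair")
  expect_null(fp$hr)
  expect_identical(fp$bp$w, 40)
})

test_that("selected boxes satisfy the filter intervals and match a brute-force scan", {
  set.seed(32)
  p <- localize_params(close = FALSE)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    boxes <- lapply(seq_len(k), function(j) {
      w <- sample(10:200, 1); h <- sample(10:200, 1)
      bbox(sample(0:(320 - w), 1), sample(0:(240 - h), 1), w, h)
    })
    img <- blob_image(240, 320, boxes)
    fp <- localize_frames(img, p)
    # brute-force reference: filter all contour boxes, take max area
    ct <- find_contours(img)
    frac <- ct$area / (240 * 320)
    cand <- ct[ct$aspect >= 0.7 & ct$aspect <= 1.4 &
                 frac >= 0.02 & frac <= 0.60, ]
    if (nrow(cand) == 0) {
      expect_null(fp)
    } else {
      best <- cand[which.max(cand$area), ]
      expect_identical(fp$bp$w, as.numeric(best$w))
      expect_identical(fp$bp$x, as.numeric(best$x))
      ar <- aspect_ratio(fp$bp)
      expect_true(ar >= 0.7 && ar <= 1.4)
      # returned boxes lie within the image
      expect_true(fp$bp$x >= 0 && fp$bp$y >= 0 &&
                    fp$bp$x + fp$bp$w <= 320 && fp$bp$y + fp$bp$h <= 240)
    }
  }
})

test_that("correct_hr_box snaps into the BP column span", {
  bp <- bbox(100, 50, 200, 220)
  inside <- bbox(120, 300, 150, 100)
  expect_identical(correct_hr_box(inside, bp), inside)
  left <- correct_hr_box(bbox(60, 300, 150, 100), bp)
  expect_identical(left$x, 100)
  expect_identical(left$w, 150)
  above <- correct_hr_box(bbox(120, 20, 150, 100), bp)
  expect_identical(above$y, 50)
  wide <- correct_hr_box(bbox(60, 300, 400, 100), bp)
  expect_identical(wide$x, 100)
  expect_identical(wide$w, 200)  # clipped to the BP width
})
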