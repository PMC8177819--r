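# Seven-segment rendering, degradations and dataset generation.

test_that("digit glyphs light exactly the canonical segments", {
  masks <- segment_masks(40)
  seg_count <- function(d) length(attr(render_digit(d, height = 40), "segments"))
  expect_identical(seg_count(8), 7L)
  expect_identical(attr(render_digit(1, height = 40), "segments"), c("B", "C"))
  expect_identical(seg_count(0), 6L)
  # middle segment off for 0
  g0 <- render_digit(0, height = 40)
  expect_true(all(g0[masks$G] == 0))
  # glyph pixels are exactly the union of the lit segment masks
  for (d in 0:9) {
    g <- render_digit(d, height = 40)
    lit <- Reduce(`|`, masks[attr(g, "segments")])
    expect_identical(unname(g > 0), unname(lit))
  }
  # segments are disconnected strokes: no two masks overlap
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1))
  expect_true(all(overlap <= 1))
})

test_that("non-digit input is rejected", {
  expect_error(render_digit(10), "digit")
  expect_error(render_digit(-1), "digit")
  expect_error(render_digit(3.5), "digit")
})

test_that("clean scenes are invertible at the label level", {
  # cropping the ink pixels of each value region recovers the rendered
  # glyph pattern exactly (pixel-set equality)
  sc <- render_scene(list(sbp = 120, dbp = 80, hr = 72), noise_sd = 0)
  L <- sc$layout
  ink <- L$shades$ink
  tight_crop <- function(rows, cols) {
    sub <- sc$image[rows, cols] == ink
    ys <- range(which(rowSums(sub) > 0)); xs <- range(which(colSums(sub) > 0))
    sub[ys[1]:ys[2], xs[1]:xs[2]]
  }
  d <- L$bp_digit
  glyphs <- function(v, dg) {
    g <- bpocr:::render_value_glyphs(v, dg$h, dg$w, dg$spacing, dg$thickness,
                                     max(1, round(dg$thickness / 2))) > 0
    ys <- range(which(rowSums(g) > 0)); xs <- range(which(colSums(g) > 0))
    g[ys[1]:ys[2], xs[1]:xs[2]]
  }
  top <- (L$lcd$y + 1):(L$lcd$y + floor(L$lcd$h / 2))
  bottom <- (L$lcd$y + floor(L$lcd$h / 2) + 1):(L$lcd$y + L$lcd$h)
  cols <- (L$lcd$x + 1):(L$lcd$x + L$lcd$w)
  expect_identical(unname(tight_crop(top, cols)), unname(glyphs(120, d)))
  expect_identical(unname(tight_crop(bottom, cols)), unname(glyphs(80, d)))
  hr_rows <- (L$hr$y + 1):(L$hr$y + L$hr$h)
  expect_identical(unname(tight_crop(hr_rows, cols)),
                   unname(glyphs(72, L$hr_digit)))
})

test_that("scene rendering is value-agnostic but rejects >3 digits", {
  expect_silent(render_scene(list(sbp = 34, dbp = 120, hr = 40), noise_sd = 0))
  expect_error(render_scene(list(sbp = 1000, dbp = 80, hr = 72)), "999")
  expect_error(render_scene(list(sbp = NaN, dbp = 80, hr = 72)))
})

test_that("equal seeds give bit-identical scenes", {
  set.seed(77)
  s1 <- render_scene(list(sbp = 117, dbp = 64, hr = 99), angle = 2.5)
  set.seed(77)
  s2 <- render_scene(list(sbp = 117, dbp = 64, hr = 99), angle = 2.5)
  expect_identical(s1$image, s2$image)
})

test_that("degradations follow their definitions", {
  set.seed(3)
  sc <- render_scene(list(sbp = 120, dbp = 80, hr = 72), noise_sd = 0)
  img <- sc$image
  # OK is the identity
  expect_equal(degrade(img, "OK"), img, ignore_attr = TRUE)
  # fixed darkening factor multiplies every pixel
  dark <- degrade(img, "D", degrade_params(dark_factor = 0.3))
  expect_equal(dark, floor(0.3 * img + 0.5), ignore_attr = TRUE)
  expect_lte(max(dark), 77)
  # FAR scales the ground-truth boxes by the recorded factor
  far <- degrade(sc, "FAR", degrade_params(far_scale = 0.4))
  expect_equal(far$lcd_box$w, 0.4 * sc$lcd_box$w, tolerance = 1e-9)
  expect_equal(far$lcd_box$h, 0.4 * sc$lcd_box$h, tolerance = 1e-9)
  # degradations preserve the canvas size
  for (lab in QUALITY_LABELS) {
    set.seed(4)
    expect_identical(dim(degrade(img, lab)), dim(img))
  }
})

test_that("sampled readings respect the annotated field range", {
  set.seed(11)
  r <- sample_reading(10000)
  expect_true(all(r$dbp >= 34 & r$dbp <= 120))
  expect_true(all(r$sbp > r$dbp))
  expect_true(all(r$sbp >= 44 & r$sbp <= 203))
  expect_gte(min(c(r$sbp, r$dbp)), 34)
  expect_lte(max(c(r$sbp, r$dbp)), 203)
  expect_true(all(r$hr >= 40 & r$hr <= 180))
  set.seed(11)
  expect_identical(sample_reading(50), {set.seed(11); sample_reading(50)})
})

test_that("generate_dataset writes consistent images and manifest", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(12, quality_mix = c(OK = 1), seed = 5, noise_sd = 2)
  manifest <- generate_dataset(spec, dir)
  expect_identical(nrow(manifest), 12L)
  expect_true(all(manifest$quality == "OK"))
  expect_true(all(file.exists(file.path(dir, manifest$filename))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  roundtrip <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(roundtrip$sbp, manifest$sbp)
  # identical spec => identical manifest and identical image bytes
  dir2 <- withr::local_tempdir()
  manifest2 <- generate_dataset(spec, dir2)
  m1 <- manifest; attr(m1, "dir") <- NULL
  m2 <- manifest2; attr(m2, "dir") <- NULL
  expect_identical(m1, m2)
  expect_identical(unname(tools::md5sum(file.path(dir, manifest$filename[3]))),
                   unname(tools::md5sum(file.path(dir2, manifest$filename[3]))))
})

test_that("quality labels are drawn from the requested mixture", {
  dir <- withr::local_tempdir()
  n <- 250
  spec <- synthetic_spec(n, seed = 9)
  manifest <- generate_dataset(spec, dir)
  mix <- default_quality_mix()
  counts <- table(factor(manifest$quality, levels = names(mix)))
  # each count within 4 multinomial standard deviations of expectation
  for (lab in names(mix)) {
    expected <- n * mix[[lab]]
    sdv <- sqrt(n * mix[[lab]] * (1 - mix[[lab]]))
    expect_lt(abs(counts[[lab]] - expected), 4 * sdv + 1)
  }
})

test_that("invalid synthetic specs are rejected", {
  expect_error(synthetic_spec(10, c(OK = 0.5)), "sum to 1")
  expect_error(synthetic_spec(10, c(WHAT = 1)), "labels")
  expect_error(synthetic_spec(0), "n_images")
})
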