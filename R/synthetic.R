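# Synthetic seven-segment scene generator.
#
# Renders 640x480 grayscale photographs of an oscillometric BP monitor:
# a large LCD frame with systolic over diastolic readings, a smaller heart-
# rate frame below, a flat device body and a darker cluttered background,
# plus the six quality degradations observed in field data (blur, dark,
# reflections, far, cropped, good). Every scene carries exact ground truth
# (reading and frame boxes), and all randomness flows through R's RNG so a
# single set.seed() makes generation bit-reproducible.

#' Quality labels of the degradation taxonomy
#' @export
QUALITY_LABELS <- c("B", "D", "R", "FAR", "CROPPED", "OK")

BLANK <- 10L  # class index of the empty digit slot (see recognize module)

#' Default quality-label mixture
#'
#' Proportions of the six quality classes as observed in the field corpus
#' the generator emulates: 740 blurred, 314 dark, 3885 with reflections,
#' 375 far, 630 cropped and 1261 good-quality images out of 7205.
#'
#' @return named numeric vector over [QUALITY_LABELS] summing to 1.
#' @export
default_quality_mix <- function() {
  counts <- c(B = 740, D = 314, R = 3885, FAR = 375, CROPPED = 630, OK = 1261)
  counts / sum(counts)
}

# --- seven-segment geometry ------------------------------------------------

# lit segments per digit; A top, B top-right, C bottom-right, D bottom,
# E bottom-left, F top-left, G middle
SEGMENT_MAP <- list(
  `0` = c("A", "B", "C", "D", "E", "F"),
  `1` = c("B", "C"),
  `2` = c("A", "B", "G", "E", "D"),
  `3` = c("A", "B", "G", "C", "D"),
  `4` = c("F", "G", "B", "C"),
  `5` = c("A", "F", "G", "C", "D"),
  `6` = c("A", "F", "G", "E", "D", "C"),
  `7` = c("A", "B", "C"),
  `8` = c("A", "B", "C", "D", "E", "F", "G"),
  `9` = c("A", "B", "C", "D", "F", "G")
)

#' Pixel masks of the seven display segments
#'
#' Builds the seven stroke masks of a seven-segment digit cell. Segments are
#' deliberately disconnected: corner gaps of `gap` pixels separate
#' horizontal from vertical strokes, as on a physical LCD.
#'
#' @param height,width cell size in pixels.
#' @param thickness stroke thickness in pixels; default scales with height.
#' @param gap corner gap in pixels; default scales with thickness.
#' @return named list of seven logical matrices (`A` ... `G`).
#' @export
segment_masks <- function(height, width = round(0.66 * height),
                          thickness = max(2, round(0.12 * height)),
                          gap = max(1, round(thickness / 2))) {
  t <- thickness; g <- gap
  if (height < 3 * t + 2 * g + 2 || width < 2 * t + 2 * g + 1) {
    stop("digit cell too small for the requested stroke geometry", call. = FALSE)
  }
  mid0 <- floor((height - t) / 2) + 1
  hx <- (t + g + 1):(width - t - g)
  uy <- (t + g + 1):(mid0 - 1 - g)
  ly <- (mid0 + t + g):(height - t - g)
  blank <- matrix(FALSE, height, width)
  seg <- function(rows, cols) {
    m <- blank
    m[rows, cols] <- TRUE
    m
  }
  list(
    A = seg(1:t, hx),
    B = seg(uy, (width - t + 1):width),
    C = seg(ly, (width - t + 1):width),
    D = seg((height - t + 1):height, hx),
    E = seg(ly, 1:t),
    F = seg(uy, 1:t),
    G = seg(mid0:(mid0 + t - 1), hx)
  )
}

#' Render a single seven-segment digit glyph
#'
#' @param d digit 0-9.
#' @inheritParams segment_masks
#' @param on intensity of lit pixels (background is 0).
#' @return binary glyph matrix (`height` x `width`) with the canonical lit
#'   segments of `d`; attribute `"segments"` lists them.
#' @examples
#' g <- render_digit(8, height = 40)
#' attr(g, "segments")
#' @export
render_digit <- function(d, height = 88, width = round(0.66 * height),
                         thickness = max(2, round(0.12 * height)),
                         gap = max(1, round(thickness / 2)), on = 255) {
  if (length(d) != 1 || is.na(d) || d %% 1 != 0 || d < 0 || d > 9) {
    stop("d must be a single digit 0-9", call. = FALSE)
  }
  masks <- segment_masks(height, width, thickness, gap)
  lit <- SEGMENT_MAP[[as.character(d)]]
  out <- matrix(0, height, width)
  for (s in lit) out[masks[[s]]] <- on
  attr(out, "segments") <- lit
  out
}

# render a 0-999 value as a right-aligned 3-slot glyph row
render_value_glyphs <- function(v, height, width, spacing, thickness, gap,
                                on = 255) {
  slots <- encode_value(v)
  total_w <- 3 * width + 2 * spacing
  out <- matrix(0, height, total_w)
  for (i in 1:3) {
    if (slots[i] == BLANK) next
    x0 <- (i - 1) * (width + spacing)
    out[, (x0 + 1):(x0 + width)] <-
      render_digit(slots[i], height, width, thickness, gap, on = on)
  }
  out
}

# --- device layout ---------------------------------------------------------

#' Describe the monitor geometry inside the photograph
#'
#' Mirrors the physical device: a roughly square BP display holding the
#' systolic value above the diastolic one, with a wider-than-tall heart-rate
#' frame below it, both inset in a large flat device body. Digit sizes are
#' derived from the frame sizes (BP digits fill roughly the top/bottom
#' halves of the BP frame; HR digits are proportionally smaller).
#'
#' @param image_w,image_h canvas size in pixels.
#' @param lcd_x,lcd_y,lcd_w,lcd_h BP frame box (pixels). The default frame
#'   size sits inside the 137x146 to 264x303 px range observed at this
#'   canvas size.
#' @param border frame border thickness in pixels.
#' @param shades display intensities (background, body, LCD background,
#'   digit ink, frame border).
#' @return object of class `"device_layout"`.
#' @export
device_layout <- function(image_w = 640, image_h = 480,
                          lcd_x = 220, lcd_y = 80, lcd_w = 200, lcd_h = 220,
                          border = 4,
                          shades = list(bg = 120, body = 200, lcd_bg = 225,
                                        ink = 30, frame = 40)) {
  pad <- 4
  hr_h <- round(0.52 * lcd_h)
  hr <- bbox(lcd_x, lcd_y + lcd_h + 10, lcd_w, hr_h)
  if (hr$y + hr$h > image_h - 4) {
    stop("layout does not fit the canvas", call. = FALSE)
  }
  inner_w <- lcd_w - 2 * (border + pad)
  half_h <- floor((lcd_h - 2 * (border + pad)) / 2)
  bp_h <- min(round(0.42 * lcd_h), half_h - 2)
  bp_sp <- max(3, round(0.03 * lcd_w))
  bp_w <- min(round(0.66 * bp_h), floor((inner_w - 2 * bp_sp) / 3))
  hr_dh <- min(round(0.49 * hr_h), hr_h - 2 * (border + pad) - 2)
  hr_sp <- max(2, round(0.02 * lcd_w))
  hr_dw <- min(round(0.66 * hr_dh), floor((inner_w - 2 * hr_sp) / 3))
  structure(list(
    image_w = image_w, image_h = image_h,
    body = bbox(30, 8, image_w - 60, image_h - 16),
    lcd = bbox(lcd_x, lcd_y, lcd_w, lcd_h),
    hr = hr,
    border = border, pad = pad,
    bp_digit = list(h = bp_h, w = bp_w, spacing = bp_sp,
                    thickness = max(2, round(0.12 * bp_h))),
    hr_digit = list(h = hr_dh, w = hr_dw, spacing = hr_sp,
                    thickness = max(2, round(0.12 * hr_dh))),
    shades = shades
  ), class = "device_layout")
}

# sample a plausible layout (frame size / position jitter between scenes)
sample_layout <- function() {
  lcd_w <- round(runif(1, 170, 230))
  lcd_y <- round(runif(1, 55, 100))
  max_h <- floor((474 - 12 - lcd_y) / 1.52)
  lcd_h <- round(lcd_w * runif(1, 1.02, min(1.25, max_h / lcd_w)))
  lcd_x <- round(runif(1, 180, 640 - 180 - lcd_w))
  device_layout(lcd_x = lcd_x, lcd_y = lcd_y, lcd_w = lcd_w, lcd_h = lcd_h)
}

# draw a rectangular frame: border ring + interior fill
draw_frame <- function(img, box, border, fill, ring) {
  img <- fill_box(img, box, ring)
  inner <- bbox(box$x + border, box$y + border,
                box$w - 2 * border, box$h - 2 * border)
  fill_box(img, inner, fill)
}

# paste a glyph block so its right edge sits at x_right (0-based, exclusive)
# and its vertical centre at y_mid
paste_glyphs <- function(img, glyphs, x_right, y_mid, ink) {
  gh <- nrow(glyphs); gw <- ncol(glyphs)
  y0 <- round(y_mid - gh / 2)
  x0 <- x_right - gw
  rows <- (y0 + 1):(y0 + gh)
  cols <- (x0 + 1):(x0 + gw)
  patch <- img[rows, cols]
  patch[glyphs > 0] <- ink
  img[rows, cols] <- patch
  img
}

#' Render a synthetic BP-monitor photograph
#'
#' Draws the device body, the BP frame with the systolic value over the
#' diastolic value, the heart-rate frame, then applies an optional in-plane
#' rotation (parallax stand-in) and additive sensor noise. Ground-truth
#' boxes are returned after the same geometric transform, as axis-aligned
#' hulls clipped to the canvas.
#'
#' Rendering is value-agnostic: any triple of 0-999 values is drawn, even
#' physiologically impossible ones. Randomness is consumed only for the
#' noise term, so `noise_sd = 0` renders deterministically without touching
#' the RNG stream.
#'
#' @param reading list or vector with `sbp`, `dbp`, `hr`, each an integer
#'   in \[0, 999\].
#' @param layout a [device_layout()].
#' @param angle in-plane rotation in degrees.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @return object of class `"bp_scene"`: `image`, `reading`, `lcd_box`,
#'   `hr_box`, `angle`, `quality` (initially `"OK"`), `layout`.
#' @examples
#' sc <- render_scene(list(sbp = 120, dbp = 80, hr = 72), noise_sd = 0)
#' dim(sc$image)
#' @export
render_scene <- function(reading, layout = device_layout(), angle = 0,
                         noise_sd = 4) {
  reading <- as.list(reading)[c("sbp", "dbp", "hr")]
  vals <- unlist(reading)
  if (any(is.na(vals)) || any(vals %% 1 != 0) || any(vals < 0) ||
      any(vals > 999)) {
    stop("reading values must be integers in [0, 999] (at most 3 digits)",
         call. = FALSE)
  }
  L <- layout
  sh <- L$shades
  img <- matrix(sh$bg, L$image_h, L$image_w)
  img <- fill_box(img, L$body, sh$body)
  img <- draw_frame(img, L$lcd, L$border, sh$lcd_bg, sh$frame)
  img <- draw_frame(img, L$hr, L$border, sh$lcd_bg, sh$frame)

  d <- L$bp_digit
  x_right <- L$lcd$x + L$lcd$w - L$border - L$pad
  top_mid <- L$lcd$y + L$border + L$pad + (L$lcd$h / 2 - L$border - L$pad) / 2
  bot_mid <- L$lcd$y + L$lcd$h / 2 + (L$lcd$h / 2 - L$border - L$pad) / 2
  img <- paste_glyphs(img,
    render_value_glyphs(reading$sbp, d$h, d$w, d$spacing, d$thickness,
                        max(1, round(d$thickness / 2))),
    x_right, top_mid, sh$ink)
  img <- paste_glyphs(img,
    render_value_glyphs(reading$dbp, d$h, d$w, d$spacing, d$thickness,
                        max(1, round(d$thickness / 2))),
    x_right, bot_mid, sh$ink)
  dh <- L$hr_digit
  hr_right <- L$hr$x + L$hr$w - L$border - L$pad
  hr_mid <- L$hr$y + L$hr$h / 2
  img <- paste_glyphs(img,
    render_value_glyphs(reading$hr, dh$h, dh$w, dh$spacing, dh$thickness,
                        max(1, round(dh$thickness / 2))),
    hr_right, hr_mid, sh$ink)

  lcd_box <- L$lcd
  hr_box <- L$hr
  if (angle != 0) {
    th <- angle * pi / 180
    cx <- (L$image_w - 1) / 2
    cy <- (L$image_h - 1) / 2
    inv <- c(cos(th), sin(th), cx - cos(th) * cx - sin(th) * cy,
             -sin(th), cos(th), cy + sin(th) * cx - cos(th) * cy)
    img <- warp_affine_cpp(img, inv, sh$bg)
    rot_box <- function(b) {
      xs <- c(b$x, b$x + b$w, b$x, b$x + b$w)
      ys <- c(b$y, b$y, b$y + b$h, b$y + b$h)
      rx <- cos(th) * (xs - cx) - sin(th) * (ys - cy) + cx
      ry <- sin(th) * (xs - cx) + cos(th) * (ys - cy) + cy
      clip_box(bbox(min(rx), min(ry), max(rx) - min(rx), max(ry) - min(ry)),
               L$image_w, L$image_h)
    }
    lcd_box <- rot_box(lcd_box)
    hr_box <- rot_box(hr_box)
  }
  if (noise_sd > 0) {
    img <- clamp255(round_half_up(img + matrix(
      rnorm(length(img), 0, noise_sd), nrow(img), ncol(img))))
  }
  structure(list(image = img, reading = reading, lcd_box = lcd_box,
                 hr_box = hr_box, angle = angle, quality = "OK",
                 layout = L),
            class = "bp_scene")
}

# --- degradations ----------------------------------------------------------

#' Degradation parameter ranges
#'
#' Ranges for the five non-identity quality transforms. A length-1 value
#' fixes the parameter; a length-2 value is sampled uniformly per image.
#'
#' @param blur_sigma Gaussian blur sigma (px) for label `"B"`.
#' @param dark_factor global intensity multiplier (< 1) for `"D"`.
#' @param glare_count,glare_radius,glare_peak elliptical glare patches for
#'   `"R"`: how many, their radius (px) and added peak intensity.
#' @param far_scale downscale factor of the whole device for `"FAR"`.
#' @param crop_slack extra pixels cut beyond the LCD border for `"CROPPED"`.
#' @return list of class `"degrade_params"`.
#' @export
degrade_params <- function(blur_sigma = c(1.2, 2.8),
                           dark_factor = c(0.25, 0.5),
                           glare_count = c(1, 3),
                           glare_radius = c(25, 70),
                           glare_peak = c(120, 220),
                           far_scale = c(0.35, 0.6),
                           crop_slack = c(0, 4)) {
  structure(list(blur_sigma = blur_sigma, dark_factor = dark_factor,
                 glare_count = glare_count, glare_radius = glare_radius,
                 glare_peak = glare_peak, far_scale = far_scale,
                 crop_slack = crop_slack),
            class = "degrade_params")
}

draw_range <- function(r) if (length(r) == 1) r else runif(1, r[1], r[2])
draw_int_range <- function(r) {
  if (length(r) == 1) as.integer(r) else sample(r[1]:r[2], 1)
}

# core degradation on an image matrix; boxes (lcd/hr) are optional and are
# transformed alongside for FAR/CROPPED
degrade_core <- function(img, label, params, boxes = NULL, severity = 1) {
  h <- nrow(img); w <- ncol(img)
  info <- list(label = label)
  out <- img
  if (label == "OK") {
    # identity
  } else if (label == "B") {
    info$sigma <- draw_range(params$blur_sigma) * severity
    out <- gaussian_blur_cpp(img, info$sigma)
  } else if (label == "D") {
    f <- draw_range(params$dark_factor)
    if (severity > 1) f <- f / (4 * severity)
    info$factor <- f
    out <- clamp255(round_half_up(f * img))
  } else if (label == "R") {
    k <- draw_int_range(params$glare_count)
    if (severity > 1) k <- k + 2
    info$patches <- vector("list", k)
    acc <- img
    for (i in seq_len(k)) {
      rad <- draw_range(params$glare_radius) * severity
      peak <- draw_range(params$glare_peak)
      if (!is.null(boxes) && runif(1) < 0.7) {
        b <- boxes$lcd
        cx <- runif(1, b$x - 0.25 * b$w, b$x + 1.25 * b$w)
        cy <- runif(1, b$y - 0.25 * b$h, b$y + 1.25 * b$h)
      } else {
        cx <- runif(1, 0, w - 1)
        cy <- runif(1, 0, h - 1)
      }
      ecc <- runif(1, 0.6, 1.6)  # elliptical eccentricity
      xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
      ys <- matrix(0:(h - 1), h, w)
      r2 <- ((xs - cx) / ecc)^2 + (ys - cy)^2
      acc <- acc + peak * exp(-r2 / (2 * (rad / 2)^2))
      info$patches[[i]] <- list(cx = cx, cy = cy, radius = rad, peak = peak,
                                ecc = ecc)
    }
    out <- clamp255(round_half_up(acc))
  } else if (label == "FAR") {
    s <- draw_range(params$far_scale) / severity
    ox <- runif(1, 0, w * (1 - s))
    oy <- runif(1, 0, h * (1 - s))
    fill <- median(img[c(1, h), c(1, w)])
    inv <- c(1 / s, 0, -ox / s, 0, 1 / s, -oy / s)
    out <- warp_affine_cpp(img, inv, fill)
    info$scale <- s; info$ox <- ox; info$oy <- oy
    if (!is.null(boxes)) {
      boxes <- lapply(boxes, function(b) {
        if (is.null(b)) return(NULL)
        clip_box(bbox(s * b$x + ox, s * b$y + oy, s * b$w, s * b$h), w, h)
      })
    }
  } else if (label == "CROPPED") {
    if (is.null(boxes)) {
      m <- round(0.12 * w)
    } else {
      m <- round(boxes$lcd$x + 4 + draw_range(params$crop_slack))
    }
    fill <- median(img[c(1, h), c(1, w)])
    inv <- c(1, 0, m, 0, 1, 0)  # shift content left by m
    out <- warp_affine_cpp(img, inv, fill)
    info$shift <- m
    if (!is.null(boxes)) {
      boxes <- lapply(boxes, function(b) {
        if (is.null(b)) return(NULL)
        clip_box(bbox(b$x - m, b$y, b$w, b$h), w, h)
      })
    }
  } else {
    stop("unknown quality label: ", label, call. = FALSE)
  }
  list(image = out, boxes = boxes, info = info)
}

#' Apply a quality degradation
#'
#' Applies the transform matching a quality label: `"OK"` is the identity,
#' `"B"` Gaussian blur, `"D"` a global darkening multiplier, `"R"` additive
#' elliptical glare patches, `"FAR"` downscales the device into a sub-region
#' of the canvas, `"CROPPED"` shifts the device so part of the LCD border
#' leaves the frame while all digits stay visible. Parameters actually drawn
#' are recorded in the result.
#'
#' @param x a `"bp_scene"` (ground-truth boxes are transformed alongside) or
#'   a plain image matrix (returned with a `"degrade_info"` attribute).
#' @param label one of [QUALITY_LABELS].
#' @param params a [degrade_params()].
#' @return degraded scene (with `quality` and `degrade_info` set) or image.
#' @export
degrade <- function(x, label, params = degrade_params()) {
  label <- match.arg(label, QUALITY_LABELS)
  if (inherits(x, "bp_scene")) {
    res <- degrade_core(x$image, label, params,
                        boxes = list(lcd = x$lcd_box, hr = x$hr_box))
    x$image <- res$image
    x$lcd_box <- res$boxes$lcd
    x$hr_box <- res$boxes$hr
    x$quality <- label
    x$degrade_info <- res$info
    x
  } else {
    assert_gray(x)
    res <- degrade_core(x, label, params)
    out <- res$image
    attr(out, "degrade_info") <- res$info
    out
  }
}

# --- value sampling and dataset generation ---------------------------------

#' Sample plausible blood-pressure readings
#'
#' Diastolic pressure uniform on \[34, 120\] mm Hg, systolic uniform on
#' \[dbp + 10, 203\] so every draw satisfies 34 <= dbp < sbp <= 203 (the
#' annotated field range), heart rate uniform on \[40, 180\] bpm; all
#' integers. Uniform sampling is a stand-in for the unpublished cohort
#' distribution, not a claim about it.
#'
#' @param n number of readings.
#' @return data.frame with integer columns `sbp`, `dbp`, `hr`.
#' @export
sample_reading <- function(n = 1) {
  dbp <- sample(34:120, n, replace = TRUE)
  sbp <- dbp + 10L + as.integer(floor(runif(n) * (203 - dbp - 10 + 1)))
  hr <- sample(40:180, n, replace = TRUE)
  data.frame(sbp = as.integer(sbp), dbp = dbp, hr = hr)
}

#' Specification of a synthetic dataset
#'
#' @param n_images number of scenes.
#' @param quality_mix named proportions over [QUALITY_LABELS]; must sum to 1.
#' @param seed RNG seed governing every random choice.
#' @param angle_range in-plane rotation range (degrees) applied to all
#'   quality classes.
#' @param noise_sd additive pixel-noise standard deviation.
#' @param degrade a [degrade_params()].
#' @param unreadable_rate fraction of images pushed to unreadable extremes
#'   (their values become NaN in the manifest); 0 keeps every image
#'   readable, which is the regime the recognizer is evaluated in.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_images, quality_mix = default_quality_mix(),
                           seed = 1, angle_range = c(-5, 5), noise_sd = 4,
                           degrade = degrade_params(), unreadable_rate = 0) {
  if (abs(sum(quality_mix) - 1) > 1e-8) {
    stop("quality_mix must sum to 1", call. = FALSE)
  }
  if (is.null(names(quality_mix)) || !all(names(quality_mix) %in% QUALITY_LABELS)) {
    stop("quality_mix must be named with quality labels", call. = FALSE)
  }
  if (n_images < 1) stop("n_images must be >= 1", call. = FALSE)
  if (diff(range(angle_range)) < 0) stop("degenerate angle_range", call. = FALSE)
  structure(list(n_images = n_images, quality_mix = quality_mix, seed = seed,
                 angle_range = angle_range, noise_sd = noise_sd,
                 degrade = degrade, unreadable_rate = unreadable_rate),
            class = "synthetic_spec")
}

# draw one scene under a spec (RNG state is the caller's responsibility)
synth_scene <- function(spec) {
  reading <- as.list(sample_reading(1))
  layout <- sample_layout()
  angle <- runif(1, spec$angle_range[1], spec$angle_range[2])
  quality <- sample(names(spec$quality_mix), 1, prob = spec$quality_mix)
  unreadable <- spec$unreadable_rate > 0 && runif(1) < spec$unreadable_rate
  if (unreadable && quality == "OK") quality <- "D"  # an extreme always exists
  scene <- render_scene(reading, layout, angle = angle,
                        noise_sd = spec$noise_sd)
  res <- degrade_core(scene$image, quality, spec$degrade,
                      boxes = list(lcd = scene$lcd_box, hr = scene$hr_box),
                      severity = if (unreadable) 3 else 1)
  scene$image <- res$image
  scene$lcd_box <- res$boxes$lcd
  scene$hr_box <- res$boxes$hr
  scene$quality <- quality
  scene$degrade_info <- res$info
  scene$readability <- if (unreadable) {
    switch(quality, B = "O", D = "D", R = "R", "N")
  } else {
    "READABLE"
  }
  scene
}

manifest_row <- function(filename, scene) {
  na_if_unreadable <- function(v) {
    if (identical(scene$readability, "READABLE")) v else NA_integer_
  }
  lcd <- scene$lcd_box
  hr <- scene$hr_box
  data.frame(
    filename = filename,
    sbp = na_if_unreadable(scene$reading$sbp),
    dbp = na_if_unreadable(scene$reading$dbp),
    hr = na_if_unreadable(scene$reading$hr),
    quality = scene$quality,
    readability = scene$readability,
    lcd_x = if (is.null(lcd)) NA else lcd$x,
    lcd_y = if (is.null(lcd)) NA else lcd$y,
    lcd_w = if (is.null(lcd)) NA else lcd$w,
    lcd_h = if (is.null(lcd)) NA else lcd$h,
    hr_x = if (is.null(hr)) NA else hr$x,
    hr_y = if (is.null(hr)) NA else hr$y,
    hr_w = if (is.null(hr)) NA else hr$w,
    hr_h = if (is.null(hr)) NA else hr$h,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic image dataset on disk
#'
#' Renders `spec$n_images` scenes, applies quality degradations drawn from
#' `spec$quality_mix`, writes each as an 8-bit grayscale PNG and a manifest
#' CSV (`manifest.csv`) with one row per image: filename, ground-truth
#' values, quality and readability labels, and the BP/HR frame boxes.
#' Unreadable values are written as empty fields. Deterministic under
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest data.frame, invisibly; attribute `"dir"` holds
#'   `out_dir`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  set.seed(spec$seed)
  rows <- vector("list", spec$n_images)
  for (i in seq_len(spec$n_images)) {
    scene <- synth_scene(spec)
    fn <- sprintf("img_%05d.png", i)
    write_image(scene$image, file.path(out_dir, fn))
    rows[[i]] <- manifest_row(fn, scene)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

#' Write / read a dataset manifest
#'
#' CSV with header `filename,sbp,dbp,hr,quality,readability,lcd_x,lcd_y,
#' lcd_w,lcd_h,hr_x,hr_y,hr_w,hr_h`; NaN/NA values are encoded as empty
#' fields.
#'
#' @param manifest manifest data.frame.
#' @param path CSV file path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the
#'   manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(filename = "character", quality = "character",
                          readability = "character"))
}
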