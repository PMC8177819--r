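# Image enhancement: raw photograph -> binary image in which LCD frame
# borders and digit strokes are foreground. Four stages, applied in order:
# grayscale conversion, edge-preserving bilateral smoothing, power-law
# (gamma) intensity correction, and locally adaptive mean thresholding.

#' Enhancement parameters
#'
#' The published pipeline fixes the stage order but not the parameter
#' values; these defaults are conventional choices at the LCD pixel scale
#' (frames of roughly 140-300 px in a 640x480 photograph) and are exposed
#' so every one can be overridden.
#'
#' @param diameter bilateral filter neighborhood diameter in pixels (odd).
#' @param sigma_range bilateral intensity sigma (intensity units).
#' @param sigma_spatial bilateral spatial sigma (pixels).
#' @param gamma exponent of the power-law correction; > 1 darkens midtones.
#' @param block_size adaptive-threshold window side in pixels (odd, >= 3).
#' @param C adaptive-threshold offset: a pixel must clear the local mean by
#'   more than `C` to become foreground.
#' @param polarity `"inverse"` marks pixels darker than their surroundings
#'   as foreground (dark LCD strokes on a light display), `"direct"` the
#'   opposite.
#' @return list of class `"enhance_params"`.
#' @export
enhance_params <- function(diameter = 9, sigma_range = 75, sigma_spatial = 75,
                           gamma = 1.2, block_size = 31, C = 5,
                           polarity = c("inverse", "direct")) {
  polarity <- match.arg(polarity)
  if (diameter < 1) stop("diameter must be >= 1", call. = FALSE)
  if (sigma_range <= 0 || sigma_spatial <= 0) {
    stop("bilateral sigmas must be positive", call. = FALSE)
  }
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (block_size < 3 || block_size %% 2 == 0) {
    stop("block_size must be odd and >= 3", call. = FALSE)
  }
  structure(list(diameter = diameter, sigma_range = sigma_range,
                 sigma_spatial = sigma_spatial, gamma = gamma,
                 block_size = block_size, C = C, polarity = polarity),
            class = "enhance_params")
}

#' Convert an image to grayscale
#'
#' Three-channel arrays are combined with the standard luminance weights
#' 0.299 R + 0.587 G + 0.114 B and rounded; grayscale matrices pass through
#' unchanged.
#'
#' @param img grayscale matrix or `h x w x 3` array in \[0, 255\].
#' @return grayscale image matrix.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3 && d[3] == 1) return(img[, , 1])
  if (length(d) != 3 || d[3] != 3) {
    stop("expected a grayscale matrix or a 3-channel array", call. = FALSE)
  }
  round_half_up(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Edge-preserving bilateral filter
#'
#' Each output pixel is the normalized sum of its diameter-neighborhood,
#' weighted by spatial proximity (`exp(-d^2 / 2 sigma_spatial^2)`) and by
#' intensity proximity (`exp(-di^2 / 2 sigma_range^2)`), so smoothing stops
#' at strong edges. Edge pixels are replicated at the border.
#'
#' @param img grayscale image matrix.
#' @param diameter neighborhood diameter in pixels.
#' @param sigma_range intensity standard deviation.
#' @param sigma_spatial spatial standard deviation in pixels.
#' @return filtered grayscale image.
#' @export
bilateral_filter <- function(img, diameter = 9, sigma_range = 75,
                             sigma_spatial = 75) {
  assert_gray(img)
  if (sigma_range <= 0 || sigma_spatial <= 0) {
    stop("sigmas must be positive", call. = FALSE)
  }
  if (diameter < 1) stop("diameter must be >= 1", call. = FALSE)
  bilateral_filter_cpp(img, as.integer(diameter), sigma_range, sigma_spatial)
}

#' Gamma (power-law) intensity correction
#'
#' Applies `O = (I / 255)^gamma * 255` per pixel, rounded half away from
#' zero and clamped. Fixes 0 and 255 for every gamma and is the identity at
#' `gamma = 1`.
#'
#' @param img grayscale image matrix.
#' @param gamma positive exponent.
#' @return corrected image.
#' @export
gamma_correct <- function(img, gamma = 1.2) {
  assert_gray(img)
  if (length(gamma) != 1 || is.na(gamma) || gamma <= 0) {
    stop("gamma must be a single positive number", call. = FALSE)
  }
  clamp255(round_half_up((img / 255)^gamma * 255))
}

#' Locally adaptive mean thresholding
#'
#' The threshold of each pixel is the arithmetic mean of its
#' `block_size x block_size` neighborhood (edge replication at the image
#' border). With `"inverse"` polarity a pixel becomes foreground (255) iff
#' its intensity is strictly below `local mean - C`; with `"direct"`, iff
#' strictly above `local mean + C`.
#'
#' @inheritParams enhance_params
#' @param img grayscale image matrix.
#' @return binary image with values in \{0, 255\}.
#' @export
adaptive_threshold <- function(img, block_size = 31, C = 5,
                               polarity = c("inverse", "direct")) {
  assert_gray(img)
  polarity <- match.arg(polarity)
  if (block_size < 3 || block_size %% 2 == 0) {
    stop("block_size must be odd and >= 3", call. = FALSE)
  }
  adaptive_threshold_cpp(img, as.integer(block_size), C,
                         polarity == "inverse")
}

#' Full enhancement chain
#'
#' Grayscale conversion, bilateral filtering, gamma correction and adaptive
#' thresholding, in that order. Deterministic: identical input and
#' parameters give identical output.
#'
#' @param img image matrix or 3-channel array.
#' @param params an [enhance_params()].
#' @return binary image (\{0, 255\}, foreground = 255).
#' @examples
#' sc <- render_scene(list(sbp = 120, dbp = 80, hr = 72), noise_sd = 0)
#' bin <- enhance(sc$image)
#' table(bin)
#' @export
enhance <- function(img, params = enhance_params()) {
  stopifnot(inherits(params, "enhance_params"))
  g <- to_grayscale(img)
  g <- bilateral_filter(g, params$diameter, params$sigma_range,
                        params$sigma_spatial)
  g <- gamma_correct(g, params$gamma)
  adaptive_threshold(g, params$block_size, params$C, params$polarity)
}
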