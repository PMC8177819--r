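# Shared helpers: images are numeric matrices (rows = y, cols = x) with
# intensities in [0, 255]; binary images use {0, 255}, foreground = 255.
# Bounding boxes are 0-based, half-open: [x, x+w) x [y, y+h).

# round half away from zero (all pipeline intensities are non-negative)
round_half_up <- function(x) floor(x + 0.5)

clamp255 <- function(x) pmin(pmax(x, 0), 255)

is_gray_image <- function(img) {
  is.matrix(img) && is.numeric(img) && nrow(img) >= 1 && ncol(img) >= 1
}

is_binary_image <- function(img) {
  is_gray_image(img) && all(img %in% c(0, 255))
}

assert_gray <- function(img) {
  if (!is_gray_image(img)) stop("expected a grayscale image matrix", call. = FALSE)
  invisible(img)
}

assert_binary <- function(img) {
  if (!is_binary_image(img)) {
    stop("expected a binary image with values in {0, 255}", call. = FALSE)
  }
  invisible(img)
}

#' Construct a bounding box
#'
#' Boxes are axis-aligned pixel rectangles, 0-based and half-open:
#' the box covers columns `[x, x + w)` and rows `[y, y + h)`.
#'
#' @param x,y top-left corner (0-based column / row).
#' @param w,h width and height in pixels (at least 1).
#' @return An object of class `"bbox"`: a list with fields `x`, `y`, `w`, `h`.
#' @examples
#' b <- bbox(5, 5, 20, 10)
#' aspect_ratio(b)
#' @export
bbox <- function(x, y, w, h) {
  x <- as.numeric(x); y <- as.numeric(y); w <- as.numeric(w); h <- as.numeric(h)
  if (w < 1 || h < 1) stop("box width and height must be >= 1", call. = FALSE)
  structure(list(x = x, y = y, w = w, h = h), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%g y=%g w=%g h=%g (aspect %.3f)>\n",
              x$x, x$y, x$w, x$h, x$w / x$h))
  invisible(x)
}

#' Width/height aspect ratio of a bounding box
#'
#' @param b a [bbox()] (or any list with `w` and `h` fields).
#' @return `w / h` as a number.
#' @export
aspect_ratio <- function(b) b$w / b$h

#' Intersection-over-union of two bounding boxes
#'
#' @param a,b boxes as created by [bbox()].
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  if (union <= 0) return(0)
  inter / union
}

# clip a box to an image extent; returns NULL if nothing remains
clip_box <- function(b, img_w, img_h) {
  x0 <- max(0, b$x); y0 <- max(0, b$y)
  x1 <- min(img_w, b$x + b$w); y1 <- min(img_h, b$y + b$h)
  if (x1 - x0 < 1 || y1 - y0 < 1) return(NULL)
  bbox(x0, y0, x1 - x0, y1 - y0)
}

# fill a box region of an image matrix with a value (1-based R indexing glue)
fill_box <- function(img, b, value) {
  rows <- (b$y + 1):(b$y + b$h)
  cols <- (b$x + 1):(b$x + b$w)
  img[rows, cols] <- value
  img
}

#' Read a grayscale image from a PNG or JPEG-free PNG file
#'
#' Reads an 8-bit PNG and returns an intensity matrix in \[0, 255\]. Color
#' images are converted with the standard luminance weights via
#' [to_grayscale()].
#'
#' @param path file path to a PNG image.
#' @return a grayscale image matrix.
#' @export
read_image <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) {
    arr <- arr[, , seq_len(min(3, dim(arr)[3])), drop = FALSE]
    if (dim(arr)[3] == 1) arr <- arr[, , 1]
  }
  img <- round_half_up(arr * 255)
  if (length(dim(img)) == 3) to_grayscale(img) else img
}

#' Write an image matrix to a PNG file
#'
#' @param img grayscale image matrix with intensities in \[0, 255\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_gray(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
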