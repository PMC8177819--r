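# Frame normalization: crop the localized frames, scale to a fixed canvas,
# strip residual frame borders, and split the BP frame into its systolic
# (top) and diastolic (bottom) halves. Every frame leaving this module is
# a 180-column x 80-row binary image, the recognizer's input size.

#' Normalization parameters
#'
#' @param frame_w,frame_h target frame size in pixels (columns x rows). The
#'   default 180 x 80 is the recognizer input: a 3-digit value is roughly
#'   twice as wide as tall, so the long side is horizontal.
#' @param trim_frac fraction of each frame dimension removed from every edge
#'   after scaling, stripping the residual LCD border included in the
#'   localized box (the published pipeline removed a fixed, unreported
#'   number of rows/columns).
#' @return list of class `"normalize_params"`.
#' @export
normalize_params <- function(frame_w = 180, frame_h = 80, trim_frac = 0.04) {
  if (frame_w < 2 || frame_h < 2) stop("targets must be >= 2", call. = FALSE)
  if (trim_frac < 0 || trim_frac >= 0.5) {
    stop("trim_frac must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(frame_w = frame_w, frame_h = frame_h, trim_frac = trim_frac),
            class = "normalize_params")
}

#' Extract a sub-image
#'
#' Returns the half-open box `[x, x+w) x [y, y+h)` of a binary image.
#'
#' @param bin binary image.
#' @param box a [bbox()] within the image extent.
#' @return binary image of size `box$h` x `box$w`.
#' @export
extract_frame <- function(bin, box) {
  assert_binary(bin)
  if (box$x < 0 || box$y < 0 || box$x + box$w > ncol(bin) ||
      box$y + box$h > nrow(bin)) {
    stop("box exceeds image extent", call. = FALSE)
  }
  bin[(box$y + 1):(box$y + box$h), (box$x + 1):(box$x + box$w), drop = FALSE]
}

#' Scale a binary frame to a fixed size
#'
#' Bilinear resampling to `target_w` columns x `target_h` rows, then
#' re-binarization at the intensity midpoint (127.5) to restore the
#' \{0, 255\} invariant.
#'
#' @param frame binary image.
#' @param target_w,target_h output size (positive).
#' @return binary image of exactly the target size.
#' @export
scale_to_fixed <- function(frame, target_w = 180, target_h = 80) {
  assert_binary(frame)
  if (target_w < 1 || target_h < 1) {
    stop("target dimensions must be positive", call. = FALSE)
  }
  s <- resize_bilinear_cpp(frame, as.integer(target_h), as.integer(target_w))
  out <- matrix(0, target_h, target_w)
  out[s > 127.5] <- 255
  out
}

#' Trim frame borders
#'
#' Removes `trim_rows` rows from the top and bottom and `trim_cols` columns
#' from the left and right.
#'
#' @param frame binary image.
#' @param trim_rows,trim_cols non-negative strip counts; at least one row
#'   and column must remain.
#' @return trimmed binary image.
#' @export
trim_border <- function(frame, trim_rows, trim_cols) {
  assert_binary(frame)
  h <- nrow(frame); w <- ncol(frame)
  if (trim_rows < 0 || trim_cols < 0 ||
      2 * trim_rows >= h || 2 * trim_cols >= w) {
    stop("trims must leave at least one row and column", call. = FALSE)
  }
  frame[(trim_rows + 1):(h - trim_rows), (trim_cols + 1):(w - trim_cols),
        drop = FALSE]
}

#' Split a BP frame into systolic and diastolic halves
#'
#' The BP display stacks the systolic value over the diastolic one, so the
#' frame is divided at half its vertical height: rows `[0, floor(h/2))` give
#' the systolic image, the remaining rows the diastolic one (for odd
#' heights the bottom half gets the extra row). Each half is then scaled to
#' the recognizer input size.
#'
#' @param frame binary BP frame (height >= 2).
#' @param target_w,target_h output size of each half.
#' @return list with binary frames `sbp` and `dbp`, each
#'   `target_h` x `target_w`.
#' @export
split_bp_frame <- function(frame, target_w = 180, target_h = 80) {
  assert_binary(frame)
  h <- nrow(frame)
  if (h < 2) stop("frame height must be >= 2", call. = FALSE)
  cut <- floor(h / 2)
  list(
    sbp = scale_to_fixed(frame[1:cut, , drop = FALSE], target_w, target_h),
    dbp = scale_to_fixed(frame[(cut + 1):h, , drop = FALSE], target_w, target_h)
  )
}

#' Normalize localized frames into recognizer inputs
#'
#' For the BP frame: crop, scale to a double-height canvas
#' (`frame_w` x `2 frame_h`), trim the scaled border, split into systolic
#' and diastolic halves and scale each to `frame_w` x `frame_h`. The HR
#' frame (when present) is cropped, scaled to the same canvas size, trimmed
#' and rescaled so one recognizer serves all three values.
#'
#' @param bin enhanced binary image.
#' @param frames a `"frame_pair"` from [localize_frames()].
#' @param params a [normalize_params()].
#' @return list of binary `frame_h` x `frame_w` frames: `sbp`, `dbp` and
#'   `hr` (`NULL` when no HR box was found).
#' @export
normalize_frames <- function(bin, frames, params = normalize_params()) {
  stopifnot(inherits(frames, "frame_pair"))
  stopifnot(inherits(params, "normalize_params"))
  w <- params$frame_w; h <- params$frame_h
  tr <- round(params$trim_frac * 2 * h)
  tc <- round(params$trim_frac * w)
  bp <- extract_frame(bin, frames$bp)
  bp <- scale_to_fixed(bp, w, 2 * h)
  bp <- trim_border(bp, tr, tc)
  halves <- split_bp_frame(bp, w, h)
  hr <- NULL
  if (!is.null(frames$hr)) {
    hr <- extract_frame(bin, frames$hr)
    hr <- scale_to_fixed(hr, w, h)
    hr <- trim_border(hr, round(params$trim_frac * h), tc)
    hr <- scale_to_fixed(hr, w, h)
  }
  list(sbp = halves$sbp, dbp = halves$dbp, hr = hr)
}
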