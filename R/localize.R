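# LCD frame localization: find the BP and heart-rate frame bounding boxes
# in the enhanced binary image by filtering connected-component boxes on
# aspect ratio and size.

#' Localization parameters
#'
#' Candidate boxes are filtered on the width/height aspect ratio and on the
#' box-area fraction of the image. The published pipeline decided its
#' thresholds on ~500 held-back images without reporting them; these
#' defaults span the observed frame geometry (roughly square BP frames of
#' 137x146 to 264x303 px in a 640x480 image; a wider-than-tall, smaller HR
#' frame) with margin.
#'
#' @param bp_aspect,bp_area BP-frame aspect-ratio interval and box-area
#'   fraction interval (of total image area).
#' @param hr_aspect,hr_area the same for the heart-rate frame.
#' @param close apply one 3x3 morphological closing before contour
#'   extraction, bridging small gaps in thresholded frame borders.
#' @return list of class `"localize_params"`.
#' @export
localize_params <- function(bp_aspect = c(0.7, 1.4), bp_area = c(0.02, 0.60),
                            hr_aspect = c(1.2, 3.0), hr_area = c(0.003, 0.15),
                            close = TRUE) {
  chk <- function(r, what) {
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      stop("invalid interval for ", what, call. = FALSE)
    }
  }
  chk(bp_aspect, "bp_aspect"); chk(bp_area, "bp_area")
  chk(hr_aspect, "hr_aspect"); chk(hr_area, "hr_area")
  structure(list(bp_aspect = bp_aspect, bp_area = bp_area,
                 hr_aspect = hr_aspect, hr_area = hr_area, close = close),
            class = "localize_params")
}

#' External contours of a binary image
#'
#' Extracts the 8-connected foreground components and returns each one's
#' tight axis-aligned bounding box. The size attribute used throughout
#' localization is the bounding-box area `w * h` (for hollow frame borders
#' the enclosed area, not the stroke pixel count, is what discriminates).
#' Rows are ordered by descending box area, ties broken by `(y, x)`.
#'
#' @param bin binary image (\{0, 255\}).
#' @return data.frame with columns `x`, `y`, `w`, `h` (0-based box), `npix`
#'   (foreground pixels in the component), `area` (`w * h`) and `aspect`
#'   (`w / h`); zero rows for a blank image.
#' @export
find_contours <- function(bin) {
  assert_binary(bin)
  d <- label_components_cpp(bin)
  if (nrow(d) == 0) {
    return(data.frame(x = integer(), y = integer(), w = integer(),
                      h = integer(), npix = integer(), area = numeric(),
                      aspect = numeric()))
  }
  d$area <- as.numeric(d$w) * d$h
  d$aspect <- d$w / d$h
  d <- d[order(-d$area, d$y, d$x), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Localize the BP and heart-rate LCD frames
#'
#' Optionally closes small gaps (3x3 closing), extracts contour boxes, and
#' picks as BP frame the largest box whose aspect ratio and image-area
#' fraction fall inside the BP intervals. The HR frame is the largest
#' remaining box satisfying the HR intervals, smaller than the BP box and
#' positioned below the BP digit region; it is then snapped to the BP box's
#' column span with [correct_hr_box()].
#'
#' @param bin binary image.
#' @param params a [localize_params()].
#' @return object of class `"frame_pair"`: list with `bp` ([bbox()]) and
#'   `hr` ([bbox()] or `NULL`), or `NULL` if no BP candidate exists
#'   (localization failure; callers record the image as unprocessed).
#' @export
localize_frames <- function(bin, params = localize_params()) {
  assert_binary(bin)
  stopifnot(inherits(params, "localize_params"))
  work <- if (params$close) close3x3_cpp(bin) else bin
  ct <- find_contours(work)
  if (nrow(ct) == 0) return(NULL)
  img_area <- nrow(bin) * ncol(bin)
  frac <- ct$area / img_area
  bp_ok <- ct$aspect >= params$bp_aspect[1] & ct$aspect <= params$bp_aspect[2] &
    frac >= params$bp_area[1] & frac <= params$bp_area[2]
  if (!any(bp_ok)) return(NULL)
  bi <- which(bp_ok)[1]  # rows are sorted by area desc, ties (y, x)
  bp <- bbox(ct$x[bi], ct$y[bi], ct$w[bi], ct$h[bi])

  hr_ok <- ct$aspect >= params$hr_aspect[1] & ct$aspect <= params$hr_aspect[2] &
    frac >= params$hr_area[1] & frac <= params$hr_area[2] &
    ct$area < bp$w * bp$h &
    (ct$y + ct$h / 2) > bp$y + 0.55 * bp$h  # below the BP digit region
  hr_ok[bi] <- FALSE
  hr <- NULL
  if (any(hr_ok)) {
    hi <- which(hr_ok)[1]
    hr <- correct_hr_box(bbox(ct$x[hi], ct$y[hi], ct$w[hi], ct$h[hi]), bp)
  }
  structure(list(bp = bp, hr = hr), class = "frame_pair")
}

#' Snap the heart-rate box to the BP frame
#'
#' The HR frame is small and noisy, so its coordinates are verified against
#' the (reliably detected) BP frame: the horizontal extent is snapped into
#' the BP column span `[bp$x, bp$x + bp$w]` and the top edge is forced at or
#' below `bp$y`. Width and height are preserved where possible, otherwise
#' clipped.
#'
#' @param hr,bp heart-rate and BP boxes ([bbox()]).
#' @return corrected HR box.
#' @export
correct_hr_box <- function(hr, bp) {
  w <- min(hr$w, bp$w)
  x <- min(max(hr$x, bp$x), bp$x + bp$w - w)
  y <- max(hr$y, bp$y)
  bbox(x, y, w, hr$h)
}
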