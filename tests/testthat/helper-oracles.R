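# Brute-force reference implementations, written straight from the
# operation definitions and kept independent of the package's C++ paths.

# double-loop bilateral filter with edge replication
bf_bilateral <- function(img, d, sigma_range, sigma_spatial) {
  r <- d %/% 2
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (y in 1:h) {
    for (x in 1:w) {
      c0 <- img[y, x]
      acc <- 0; norm <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          yy <- min(max(y + dy, 1), h)
          xx <- min(max(x + dx, 1), w)
          v <- img[yy, xx]
          wgt <- exp(-(dy^2 + dx^2) / (2 * sigma_spatial^2)) *
            exp(-(v - c0)^2 / (2 * sigma_range^2))
          acc <- acc + wgt * v
          norm <- norm + wgt
        }
      }
      out[y, x] <- min(255, max(0, floor(acc / norm + 0.5)))
    }
  }
  out
}

# sliding-window mean threshold with edge replication
bf_adaptive <- function(img, block_size, C, inverse = TRUE) {
  r <- block_size %/% 2
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (y in 1:h) {
    for (x in 1:w) {
      s <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          s <- s + img[min(max(y + dy, 1), h), min(max(x + dx, 1), w)]
        }
      }
      m <- s / block_size^2
      fg <- if (inverse) img[y, x] < m - C else img[y, x] > m + C
      out[y, x] <- if (fg) 255 else 0
    }
  }
  out
}

random_int_image <- function(h, w) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# place a filled rectangle (foreground 255) on a blank canvas
blob_image <- function(h, w, boxes) {
  img <- matrix(0, h, w)
  for (b in boxes) img <- fill_box(img, b, 255)
  img
}
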