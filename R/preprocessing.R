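# Canonical preprocessing: optional face crop -> BT.601 luma -> bicubic
# resize to a square canonical side (default 160).

#' Read a face image from PNG or JPEG
#'
#' Returns intensities on the uint8 [0, 255] scale: a matrix for grayscale
#' files or an h x w x 3 array (RGB order) for color files. An alpha channel
#' is dropped with a warning.
#'
#' @param path file path ending in .png, .jpg or .jpeg.
#' @return numeric matrix (grayscale) or h x w x 3 array (RGB).
#' @export
readFaceImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the 'jpeg' package")
    jpeg::readJPEG(path)
  } else stop("unsupported image format: ", ext)
  a <- a * 255
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) {
    warning("alpha channel dropped from ", basename(path))
    a <- a[, , 1:3, drop = FALSE]
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 2L) {  # gray + alpha
    warning("alpha channel dropped from ", basename(path))
    a <- a[, , 1L]
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1L]
  a
}

#' Write a grayscale image (uint8 scale) to PNG
#'
#' @param m numeric matrix in [0, 255] or a \linkS4class{GrayImage}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGrayPNG <- function(m, path) {
  if (methods::is(m, "GrayImage")) {
    m <- if (m@domain == "unit") m@pixels * 255 else m@pixels
  }
  png::writePNG(pmin(pmax(m / 255, 0), 1), path)
  invisible(path)
}

#' Convert an RGB face image to grayscale (BT.601 luma)
#'
#' Computes the luminance component Y = 0.299 R + 0.587 G + 0.114 B
#' (full-range BT.601 weights, as used when taking the Y plane of YCbCr) and
#' rounds half-up to the uint8 grid. Single-channel input is returned
#' unchanged, making the operation idempotent.
#'
#' @param img h x w x 3 numeric array (RGB, [0,255]), a plain matrix, or an
#'   h x w x 4 array whose alpha plane is dropped with a warning.
#' @return A \linkS4class{GrayImage} in the uint8 domain.
#' @export
#' @examples
#' px <- array(0, c(1, 1, 3)); px[1, 1, 1] <- 255
#' pixels(toGrayscale(px))  # round(0.299 * 255) = 76
toGrayscale <- function(img) {
  if (methods::is(img, "GrayImage")) return(img)
  if (is.matrix(img)) return(GrayImage(round(img), "uint8"))
  d <- dim(img)
  if (length(d) != 3L || !d[3] %in% c(1L, 3L, 4L))
    stop("expected a matrix or an array with 1, 3 or 4 channels")
  if (d[3] == 4L) {
    warning("alpha channel dropped before grayscale conversion")
    img <- img[, , 1:3, drop = FALSE]
  }
  if (dim(img)[3] == 1L) return(GrayImage(round(img[, , 1L]), "uint8"))
  y <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  GrayImage(pmin(floor(y + 0.5), 255), "uint8")  # round half-up
}

# Row-interpolation weight matrix for separable Catmull-Rom bicubic
# resampling (a = -0.5), with index clamping = edge replication. Rows sum to
# 1, so constant images are preserved exactly.
.cubicWeights <- function(nOut, nIn) {
  a <- -0.5
  kern <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
           ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
  }
  W <- matrix(0, nOut, nIn)
  scale <- nIn / nOut
  for (i in seq_len(nOut)) {
    s <- (i - 0.5) * scale + 0.5   # center-aligned source coordinate (1-based)
    base <- floor(s)
    for (off in -1:2) {
      j <- base + off
      wgt <- kern(s - j)
      jc <- min(max(j, 1L), nIn)
      W[i, jc] <- W[i, jc] + wgt
    }
  }
  W / rowSums(W)
}

#' Resize a grayscale image to the canonical square side
#'
#' Separable bicubic interpolation (Catmull-Rom kernel, a = -0.5) with edge
#' clamping; the canonical model input side is 160 pixels. A same-size input
#' is returned unchanged; constant images stay constant. Output intensities
#' are rounded and clipped back to the uint8 grid (bicubic overshoot is
#' clipped).
#'
#' @param img a \linkS4class{GrayImage} or numeric matrix ([0, 255]).
#' @param side output side length in pixels (default 160).
#' @return A \linkS4class{GrayImage}, side x side, uint8 domain.
#' @export
resizeCanonical <- function(img, side = 160L) {
  m <- if (methods::is(img, "GrayImage")) img@pixels else img
  side <- as.integer(side)
  if (side < 1L) stop("side must be positive")
  if (nrow(m) == side && ncol(m) == side) return(GrayImage(m, "uint8"))
  Wr <- .cubicWeights(side, nrow(m))
  Wc <- .cubicWeights(side, ncol(m))
  out <- Wr %*% m %*% t(Wc)
  GrayImage(pmin(pmax(round(out), 0), 255), "uint8")
}

#' A face detector that reports the whole frame
#'
#' The face-crop step takes a pluggable detector: a function mapping an image
#' to a data.frame of zero or more boxes with columns \code{x, y, w, h}
#' (1-based top-left corner, pixel sizes). This default detector always
#' returns one box covering the full image, i.e. cropping becomes a no-op. A
#' Viola-Jones (Haar cascade) detector can be plugged in through the same
#' contract when one is available; it is deliberately not re-implemented
#' here.
#'
#' @return A detector function.
#' @export
passThroughDetector <- function() {
  function(img) {
    d <- dim(img)
    data.frame(x = 1, y = 1, w = d[2], h = d[1])
  }
}

#' Crop the detected face region
#'
#' Applies the detector and crops the largest detected box (ties broken
#' toward the top-left-most box, rows before columns). Returns \code{NULL}
#' when the detector reports no face or fails, so callers can count the
#' sample as excluded, mirroring how detection failures are dropped from a real
#' study corpus rather than raised as errors.
#'
#' @param img numeric matrix or h x w x 3 array.
#' @param detector a detector function (see \code{\link{passThroughDetector}}).
#' @return Cropped image of the same kind as \code{img}, or \code{NULL}.
#' @export
cropFace <- function(img, detector = passThroughDetector()) {
  boxes <- tryCatch(detector(img), error = function(e) NULL)
  if (is.null(boxes) || nrow(boxes) == 0L) return(NULL)
  area <- boxes$w * boxes$h
  best <- which(area == max(area))
  if (length(best) > 1L) {
    b <- boxes[best, ]
    best <- best[order(b$y, b$x)][1L]
  }
  b <- boxes[best, ]
  rows <- b$y:(b$y + b$h - 1)
  cols <- b$x:(b$x + b$w - 1)
  if (length(dim(img)) == 3L) img[rows, cols, , drop = FALSE]
  else img[rows, cols, drop = FALSE]
}

#' Full preprocessing chain for one image file
#'
#' crop (pluggable detector) -> BT.601 grayscale -> bicubic resize to the
#' canonical side. Deterministic for a fixed detector. Returns \code{NULL}
#' when the detector excludes the sample.
#'
#' @param path image file path.
#' @param side canonical side (default 160).
#' @param detector face detector contract; default passes through.
#' @return A \linkS4class{GrayImage} or \code{NULL}.
#' @export
preprocessImage <- function(path, side = 160L, detector = passThroughDetector()) {
  img <- readFaceImage(path)
  img <- cropFace(img, detector)
  if (is.null(img)) return(NULL)
  resizeCanonical(toGrayscale(img), side)
}
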