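#' @useDynLib lifoseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coordinate convention, shared by every module in the package:
# images are numeric matrices indexed [row, col] with row = y, col = x;
# pixel coordinates in the public API are 0-based, so matrix element
# [r, c] is the pixel at (x = c - 1, y = r - 1). Crop boxes are half-open
# [x0, x1) x [y0, y1) in those 0-based coordinates.

#' Validate a grayscale image matrix
#'
#' Checks the contract every stage of the pipeline relies on: a numeric
#' matrix of at least 8 x 8 finite values on a nominal [0, 255] scale.
#'
#' @param image Numeric matrix, rows = y, columns = x.
#' @param arg Name used in error messages.
#' @return The image, invisibly.
#' @keywords internal
check_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(image) < 8L || ncol(image) < 8L)
    stop(sprintf("`%s` must be at least 8 x 8 pixels", arg), call. = FALSE)
  if (!all(is.finite(image)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(image)
}

check_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop(sprintf("`%s` must be a {0,1} matrix", arg), call. = FALSE)
  invisible(mask)
}

#' Load an image as a grayscale matrix
#'
#' Reads a PNG, TIFF or JPEG file and returns a numeric matrix
#' (rows = y, columns = x) linearly scaled to [0, 255]. Colour images
#' are reduced by the selected channel; the optic disc is brightest in
#' the red channel of fundus photographs, so \code{"red"} is the default
#' for colour input. \code{"gray"} uses the luminance
#' 0.2126 R + 0.7152 G + 0.0722 B.
#'
#' @param path Path to an image file.
#' @param channel One of \code{"red"}, \code{"green"}, \code{"blue"},
#'   \code{"gray"}. Ignored for single-channel input.
#' @return Numeric matrix in [0, 255].
#' @export
load_image <- function(path, channel = c("red", "gray", "green", "blue")) {
  channel <- match.arg(channel)
  if (!file.exists(path))
    stop("cannot read image file: ", path, call. = FALSE)
  img <- EBImage::readImage(path)  # values in [0, 1], dim (x, y[, channel])
  d <- dim(img)
  if (d[1L] == 0L || d[2L] == 0L)
    stop("zero-sized image: ", path, call. = FALSE)
  dat <- EBImage::imageData(img)
  if (length(d) == 2L) {
    m <- t(dat)
  } else {
    ch <- switch(channel, red = 1L, green = 2L, blue = 3L, gray = 0L)
    if (ch == 0L) {
      nch <- d[3L]
      if (nch >= 3L) {
        m <- t(0.2126 * dat[, , 1L] + 0.7152 * dat[, , 2L] + 0.0722 * dat[, , 3L])
      } else {
        m <- t(dat[, , 1L])
      }
    } else {
      if (d[3L] < ch) stop("image has no channel ", channel, call. = FALSE)
      m <- t(dat[, , ch])
    }
  }
  m * 255
}

#' Construct a crop box
#'
#' Half-open box \eqn{[x0, x1) \times [y0, y1)} in 0-based pixel
#' coordinates, standing in for the region of interest around a located
#' optic disc.
#'
#' @param x0,y0 Inclusive upper-left corner (0-based).
#' @param x1,y1 Exclusive lower-right corner.
#' @return A \code{crop_box} list.
#' @export
crop_box <- function(x0, y0, x1, y1) {
  stopifnot(length(x0) == 1, length(y0) == 1, length(x1) == 1, length(y1) == 1)
  if (!(x1 > x0 && y1 > y0))
    stop("crop box must satisfy x1 > x0 and y1 > y0", call. = FALSE)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "crop_box")
}

#' Crop an image to a box
#'
#' @param image Numeric matrix (rows = y).
#' @param box A [crop_box()].
#' @return Matrix of shape \code{(y1 - y0, x1 - x0)}; output pixel
#'   \code{(r, c)} equals source pixel \code{(y0 + r, x0 + c)} (0-based).
#' @export
crop <- function(image, box) {
  stopifnot(is.matrix(image), inherits(box, "crop_box"))
  if (box$x0 < 0L || box$y0 < 0L || box$x1 > ncol(image) || box$y1 > nrow(image))
    stop("crop box out of image bounds", call. = FALSE)
  image[(box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1, drop = FALSE]
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground (1) is written as 255, background (0) as 0, so the file
#' round-trips through [load_mask()] unchanged.
#'
#' @param mask A {0,1} matrix.
#' @param path Output PNG path.
#' @export
save_mask <- function(mask, path) {
  check_binary_mask(mask)
  img <- EBImage::Image(t(mask))
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

#' Read a binary mask from an image file
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path Path to a mask image.
#' @return A {0,1} matrix.
#' @export
load_mask <- function(path) {
  m <- load_image(path, channel = "gray")
  (m > 127.5) + 0
}
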