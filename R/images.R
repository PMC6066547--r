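#' RGB raster images
#'
#' The pipeline's common currency is an `image_rgb`: an H x W x 3 numeric
#' array with channel values in \[0, 255\]. Values are stored as doubles;
#' mixing and feature extraction work on floating-point intensities and
#' quantize only when an image is materialized.
#'
#' @param pixels H x W x 3 array (or H x W matrix, replicated to 3 channels)
#'   with finite values in \[0, 255\].
#' @return an object of class `image_rgb`.
#' @export
image_rgb <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_invalid("pixels must be an H x W x 3 array")
  }
  d <- dim(pixels)
  if (d[1] < 2L || d[2] < 2L) {
    stop_invalid("degenerate image: height and width must both be >= 2")
  }
  if (!all(is.finite(pixels))) stop_invalid("image contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_invalid("channel values must lie in [0, 255]")
  }
  structure(pixels, class = c("image_rgb", "array"))
}

#' @export
print.image_rgb <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_rgb %d x %d, range [%.1f, %.1f]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

is_image_rgb <- function(x) inherits(x, "image_rgb")

assert_image <- function(x, what = "image") {
  if (!is_image_rgb(x)) stop_invalid("%s must be an image_rgb object", what)
  invisible(x)
}

#' Weighted-intensity (luminance) plane of an image
#'
#' The standard luma weights 0.299 R + 0.587 G + 0.114 B. All intensity-domain
#' features (gradients, spectral bands, contrasts) are computed on this plane.
#'
#' @param image an `image_rgb`.
#' @return H x W numeric matrix.
#' @export
weighted_intensity <- function(image) {
  assert_image(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Clamp to [0, 255] and round half up to integers
#' @keywords internal
quantize_pixels <- function(x) {
  floor(pmin(pmax(x, 0), 255) + 0.5)
}

# Keys bicubic kernel, a = -0.5 (Catmull-Rom). Exactly interpolating:
# k(0) = 1, k(n) = 0 at other integers, so unit-scale resampling is identity.
cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# n_out x n_in row-stochastic resampling matrix (center-aligned, edge-clamped)
resample_matrix <- function(n_in, n_out) {
  scale <- n_in / n_out
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based source coordinate
    base <- floor(src)
    for (k in -1:2) {
      j <- base + k                          # 0-based neighbor
      w <- cubic_kernel(src - j)
      jc <- min(max(j, 0), n_in - 1) + 1     # clamp to the border pixel
      M[i, jc] <- M[i, jc] + w
    }
  }
  M / rowSums(M)
}

#' Standardize an image to a square side x side raster
#'
#' Center-crops to the largest centered square, then resamples to
#' `side` x `side` with separable bicubic interpolation (Catmull-Rom kernel).
#' Idempotent on an image that is already side x side.
#'
#' @param image an `image_rgb`.
#' @param side target side length in pixels (>= 2). Default 224, the input
#'   size of the classification networks this pipeline emulates.
#' @param quantize clamp and round the result to integer levels (default TRUE).
#' @return a side x side `image_rgb`.
#' @export
standardize <- function(image, side = 224L, quantize = TRUE) {
  assert_image(image)
  if (side < 2L) stop_invalid("side must be >= 2")
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (h == side && w == side) return(image)
  s <- min(h, w)
  r0 <- (h - s) %/% 2L
  c0 <- (w - s) %/% 2L
  cropped <- image[r0 + seq_len(s), c0 + seq_len(s), , drop = FALSE]
  if (s == side) {
    out <- unclass(cropped)
  } else {
    M <- resample_matrix(s, side)
    out <- array(0, dim = c(side, side, 3L))
    for (ch in 1:3) out[, , ch] <- M %*% cropped[, , ch] %*% t(M)
  }
  if (quantize) out <- quantize_pixels(out) else out <- pmin(pmax(out, 0), 255)
  image_rgb(out)
}

#' Read and write images
#'
#' PNG via the `png` package; ASCII PPM (P3) is supported so small fixtures
#' can live as plain text.
#'
#' @param path file path; format chosen by extension (.png or .ppm).
#' @return `read_image` returns an `image_rgb`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    image_rgb(round(a * 255))
  } else if (ext == "ppm") {
    read_ppm(path)
  } else {
    stop_invalid("unsupported image format: .%s", ext)
  }
}

#' @param image an `image_rgb`.
#' @rdname read_image
#' @export
write_image <- function(image, path) {
  assert_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(quantize_pixels(unclass(image)) / 255, path)
  } else if (ext == "ppm") {
    write_ppm(image, path)
  } else {
    stop_invalid("unsupported image format: .%s", ext)
  }
  invisible(path)
}

read_ppm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P3") stop_invalid("only ASCII PPM (P3) is supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) * (255 / maxval)
  # PPM is row-major, channel-interleaved
  a <- aperm(array(vals, dim = c(3L, w, h)), c(3L, 2L, 1L))
  image_rgb(a)
}

write_ppm <- function(image, path) {
  q <- quantize_pixels(unclass(image))
  h <- dim(q)[1]; w <- dim(q)[2]
  inter <- aperm(q, c(3L, 2L, 1L))  # channel, col, row -> interleaved rows
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(as.integer(inter), collapse = " "), con)
  invisible(path)
}
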