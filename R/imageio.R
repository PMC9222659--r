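#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities in `[0, 1]` (rows =
#' image height), carrying the bit depth of the file it was read from as an
#' attribute. All fusion, training, and metric code works on this single
#' canonical intensity domain; equations that assume 0--255 integer gray
#' levels (the saliency histogram, the metric histograms) operate on
#' [quantize_levels()] output instead.
#'
#' @param pixels numeric matrix with values in `[0, 1]`, at least 8 x 8.
#' @param source_depth integer bit depth of the originating file (default 8).
#' @return A `gray_image` object (a classed numeric matrix).
#' @export
gray_image <- function(pixels, source_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("image must be at least 8 x 8 pixels")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("intensities must lie in [0, 1]")
  }
  structure(pixels, source_depth = as.integer(source_depth),
            class = c("gray_image", class(pixels)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit source, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), attr(x, "source_depth"),
              min(x), max(x)))
  invisible(x)
}

#' Co-registered CT/MRI image pair
#'
#' Bundles two [gray_image]s assumed to be pixel-aligned. Registration is an
#' input contract, not something this package performs: the two members must
#' have identical dimensions.
#'
#' @param ct,mri `gray_image` objects (or plain `[0,1]` matrices) of equal size.
#' @return An `image_pair` object.
#' @export
image_pair <- function(ct, mri) {
  if (!inherits(ct, "gray_image")) ct <- gray_image(as.matrix(ct))
  if (!inherits(mri, "gray_image")) mri <- gray_image(as.matrix(mri))
  if (!identical(dim(ct), dim(mri))) {
    stop("registration mismatch: CT is ", paste(dim(ct), collapse = "x"),
         " but MRI is ", paste(dim(mri), collapse = "x"))
  }
  structure(list(ct = ct, mri = mri), class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair %d x %d>\n", nrow(x$ct), ncol(x$ct)))
  invisible(x)
}

rec601_luma <- c(0.299, 0.587, 0.114)

#' Read a grayscale image from PNG or TIFF
#'
#' RGB inputs are collapsed to luminance with the Rec. 601 weights; an alpha
#' channel, if present, is dropped. Intensities are returned rescaled to
#' `[0, 1]`.
#'
#' @param path path to an 8- or 16-bit PNG or TIFF file.
#' @return A [gray_image].
#' @export
load_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)")
  )
  depth <- 8L
  if (ext == "png") {
    # readPNG rescales to [0,1]; recover depth from the file header
    hdr <- readBin(path, "raw", n = 26L)
    if (length(hdr) >= 25L) depth <- as.integer(hdr[25L])
  } else {
    bps <- attr(m, "bits.per.sample")
    if (!is.null(bps)) depth <- as.integer(bps)
  }
  if (length(dim(m)) == 3L) {
    nc <- dim(m)[3L]
    m <- if (nc >= 3L) {
      m[, , 1L] * rec601_luma[1L] + m[, , 2L] * rec601_luma[2L] +
        m[, , 3L] * rec601_luma[3L]
    } else {
      m[, , 1L]
    }
  }
  if (length(m) == 0L) stop("zero-sized image in '", path, "'")
  gray_image(pmin(pmax(m, 0), 1), source_depth = depth)
}

#' Write a grayscale image to PNG or TIFF
#'
#' Intensities are quantized to `2^depth` levels (round half away from zero)
#' before writing, so a load/save round trip is exact up to
#' `1/(2^depth - 1)` per pixel. PNG output is 8-bit; 16-bit output uses TIFF.
#'
#' @param image a [gray_image] or `[0,1]` matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param depth 8 or 16.
#' @export
save_gray <- function(image, path, depth = 8L) {
  if (!depth %in% c(8L, 16L)) stop("depth must be 8 or 16")
  m <- unclass(image)
  attr(m, "source_depth") <- NULL
  lv <- 2L^depth
  q <- quantize_levels(m, lv) / (lv - 1)
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    png = {
      if (depth != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit")
      png::writePNG(q, path)
      TRUE
    },
    tif = ,
    tiff = {
      tiff::writeTIFF(q, path, bits.per.sample = as.integer(depth))
      TRUE
    },
    stop("unsupported image format '.", ext, "'")
  )
  invisible(ok)
}

#' Quantize intensities to integer gray levels
#'
#' Maps intensity `v` in `[0,1]` to `round(v * (levels - 1))` with halves
#' rounded away from zero, the boundary convention mattering because
#' `0.5 * 255 = 127.5` is a realizable midpoint.
#'
#' @param image `[0,1]` numeric matrix or array.
#' @param levels number of gray levels, at least 2 (256 for 8-bit work).
#' @return Integer array of the same shape with values in `0 .. levels - 1`.
#' @export
quantize_levels <- function(image, levels = 256L) {
  if (levels < 2L) stop("`levels` must be at least 2")
  v <- as.vector(unclass(image))
  if (anyNA(v) || min(v) < 0 || max(v) > 1) stop("intensities must lie in [0, 1]")
  q <- as.integer(floor(v * (levels - 1) + 0.5))
  d <- dim(image)
  if (is.null(d)) q else array(q, d)
}
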