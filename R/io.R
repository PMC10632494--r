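#' @include AllClasses.R
NULL

#' Read a PNG/JPEG image as an 8-bit grayscale IntensityImage
#'
#' Color inputs are reduced to luminance with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B); intensities are scaled to 0..255 and
#' quantized.
#'
#' @param path PNG or JPEG file
#' @return an \linkS4class{IntensityImage} with depth 256
#' @export
readImageGray <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)      # width x height (x channels), [0, 1]
  if (length(dim(dat)) == 3L) {
    nc <- dim(dat)[3]
    dat <- if (nc >= 3L)
      0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    else dat[, , 1]
  }
  px <- t(dat) * 255                  # rows = image rows
  intensityImage(matrix(pmin(pmax(floor(px + 0.5), 0), 255),
                        nrow(px), ncol(px)))
}

#' Write an IntensityImage as lossless PNG
#'
#' @param image an \linkS4class{IntensityImage}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeImagePNG <- function(image, path) {
  stopifnot(is(image, "IntensityImage"))
  EBImage::writeImage(EBImage::Image(t(pixels(image) / (imageDepth(image) - 1L))),
                      path, type = "png")
  invisible(path)
}

#' Serialize a HistogramSummary to a plain list (for JSON reports)
#' @param x a \linkS4class{HistogramSummary}
#' @return list of the summary fields (counts included)
#' @export
histogramAsList <- function(x) {
  stopifnot(is(x, "HistogramSummary"))
  list(mean = x@mean, sd = x@sd, entropy = x@entropy,
       occupied = x@occupied, levelRange = x@levelRange, counts = x@counts)
}
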