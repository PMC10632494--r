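#' @include AllClasses.R cnn.R
NULL

## ---------------------------------------------------------------------------
## Seeded synthetic fixtures: low-contrast chest-like phantoms for the
## enhancement operator and a separable three-class texture dataset for the
## classifier. The generators emulate statistical structure (compressed
## dynamic range; class-distinct textures), not anatomy.
## ---------------------------------------------------------------------------

.ellipseMask <- function(rows, cols, cy, cx, ry, rx) {
  yy <- matrix(seq_len(rows), rows, cols)
  xx <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

#' Synthetic low-contrast chest phantom
#'
#' Draws a bright elliptical "thoracic" region containing dark elliptical
#' lung fields on a dark background, adds Gaussian noise, and compresses the
#' whole scene into the requested intensity window — emulating the
#' compressed dynamic range of low-contrast CT / X-ray inputs whose
#' histograms are dense and narrow. Deterministic for a fixed seed.
#'
#' @param shape integer (rows, cols), at least 16 x 16 (default 128 x 128)
#' @param window intensity sub-range \code{c(low, high)} of [0, 255] into
#'   which all content is compressed (default \code{c(100, 150)})
#' @param lungEllipses number of dark lung fields (default 2)
#' @param noiseSd Gaussian noise standard deviation in intensity units
#'   before windowing (default 6)
#' @param seed integer seed
#' @return an \linkS4class{IntensityImage} with all values inside
#'   \code{window}
#' @examples
#' ph <- makePhantom(seed = 1)
#' range(pixels(ph))
#' @export
makePhantom <- function(shape = c(128L, 128L), window = c(100L, 150L),
                        lungEllipses = 2L, noiseSd = 6, seed = 0L) {
  shape <- as.integer(shape)
  if (length(window) != 2L || window[1] < 0 || window[2] > 255 ||
      window[1] >= window[2])
    stop("window must be c(low, high) with 0 <= low < high <= 255", call. = FALSE)
  if (any(shape < 16L)) stop("phantom must be at least 16 x 16", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  rows <- shape[1]; cols <- shape[2]
  withSeed(seed, {
    scene <- matrix(40, rows, cols)                        # air background
    thorax <- .ellipseMask(rows, cols, rows / 2, cols / 2,
                           0.45 * rows, 0.48 * cols)
    scene[thorax] <- 200                                   # soft tissue
    centers <- seq(0.28, 0.72, length.out = max(lungEllipses, 1L))
    for (e in seq_len(lungEllipses)) {
      lung <- .ellipseMask(rows, cols, 0.5 * rows + rnorm(1, 0, 0.02 * rows),
                           centers[e] * cols, 0.3 * rows, 0.16 * cols)
      scene[lung & thorax] <- 90                           # aerated lung
    }
    scene <- scene + rnorm(rows * cols, 0, noiseSd)
    # compress full dynamic range into the window, then clip and quantize
    lo <- window[1]; hi <- window[2]
    out <- lo + (hi - lo) * scene / 255
    out <- pmin(pmax(floor(out + 0.5), lo), hi)
    intensityImage(matrix(out, rows, cols))
  })
}

#' Default texture parameters of the three-class set
#'
#' One row per class: sinusoidal stripe frequency (cycles per image), stripe
#' amplitude, bright-blob density (expected blobs per pixel) and base
#' intensity. The classes are chosen to be separable both by simple global
#' statistics and by a small CNN.
#'
#' @param classes class identifiers (default three, mirroring a
#'   COVID-19 / normal / pneumonia chest-image vocabulary)
#' @return data.frame with columns class, stripeFreq, stripeAmp,
#'   blobDensity, baseIntensity
#' @export
defaultTextureParams <- function(classes = c("covid19", "normal", "pneumonia")) {
  data.frame(class = classes,
             stripeFreq = c(3, 9, 0),
             stripeAmp = c(50, 50, 0),
             blobDensity = c(0, 0.002, 0.008),
             baseIntensity = c(90, 120, 150))
}

#' Synthetic separable three-class texture dataset
#'
#' Generates \code{nPerClass} images per class; class c carries its
#' configured sinusoidal stripe frequency plus Poisson-placed bright blobs
#' at its density, over its base intensity, with additive Gaussian noise.
#' Labels are aligned with images and deterministic for a fixed seed.
#'
#' @param nPerClass images per class (default 20)
#' @param imageSize integer (rows, cols) (default 64 x 64)
#' @param textureParams per-class texture data.frame as returned by
#'   \code{\link{defaultTextureParams}}; rows must be distinct per class
#' @param noiseSd Gaussian noise standard deviation (default 8)
#' @param seed integer seed
#' @return a \linkS4class{LabeledImageSet}
#' @examples
#' ds <- makeClassSet(nPerClass = 2, seed = 1)
#' table(imageLabels(ds))
#' @export
makeClassSet <- function(nPerClass = 20L, imageSize = c(64L, 64L),
                         textureParams = defaultTextureParams(),
                         noiseSd = 8, seed = 0L) {
  if (nPerClass < 1L) stop("nPerClass must be >= 1", call. = FALSE)
  classes <- as.character(textureParams$class)
  if (anyDuplicated(classes))
    stop("duplicate class identifiers in textureParams", call. = FALSE)
  key <- do.call(paste, textureParams[, -1, drop = FALSE])
  if (anyDuplicated(key))
    stop("texture parameters must be distinct per class", call. = FALSE)
  rows <- as.integer(imageSize[1]); cols <- as.integer(imageSize[2])
  withSeed(seed, {
    images <- list(); labels <- character(0)
    xx <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    for (ci in seq_along(classes)) {
      tp <- textureParams[ci, ]
      for (r in seq_len(nPerClass)) {
        img <- matrix(tp$baseIntensity, rows, cols)
        if (tp$stripeFreq > 0) {
          phase <- runif(1, 0, 2 * pi)
          img <- img + tp$stripeAmp *
            sin(2 * pi * tp$stripeFreq * xx / cols + phase)
        }
        nBlobs <- rpois(1, tp$blobDensity * rows * cols)
        if (nBlobs > 0) {
          for (b in seq_len(nBlobs)) {
            cy <- runif(1, 4, rows - 3); cx <- runif(1, 4, cols - 3)
            blob <- .ellipseMask(rows, cols, cy, cx, 2.5, 2.5)
            img[blob] <- img[blob] + 80
          }
        }
        img <- img + rnorm(rows * cols, 0, noiseSd)
        img <- pmin(pmax(floor(img + 0.5), 0), 255)
        images[[length(images) + 1L]] <- intensityImage(matrix(img, rows, cols))
        labels <- c(labels, classes[ci])
      }
    }
    labeledImageSet(images, labels, classes = sort(classes))
  })
}

#' Nearest-centroid baseline on global texture statistics
#'
#' An intentionally simple classifier — mean intensity, column-mean spread
#' (vertical-stripe energy) and row-mean spread per image, z-scored, nearest
#' class centroid — used to certify that a generated class set is separable
#' independently of any CNN.
#'
#' @param dataset a \linkS4class{LabeledImageSet}
#' @return training (resubstitution) accuracy in \code{[0, 1]}
#' @export
baselineSeparability <- function(dataset) {
  stopifnot(is(dataset, "LabeledImageSet"))
  feats <- t(vapply(dataset@images, function(im) {
    px <- pixels(im)
    c(mean(px), stats::sd(colMeans(px)), stats::sd(rowMeans(px)))
  }, numeric(3)))
  feats <- scale(feats)
  labs <- imageLabels(dataset)
  centroids <- apply(feats, 2, function(col) tapply(col, labs, mean))
  d2 <- outer(seq_len(nrow(feats)), seq_len(nrow(centroids)),
              Vectorize(function(i, c) sum((feats[i, ] - centroids[c, ])^2)))
  pred <- rownames(centroids)[apply(d2, 1, which.min)]
  mean(pred == as.character(labs))
}

#' Write a class set to a directory tree
#'
#' One subdirectory per class containing PNG files — the dataset layout the
#' training CLI consumes (class vocabulary = sorted directory names).
#'
#' @param dataset a \linkS4class{LabeledImageSet}
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
writeClassSet <- function(dataset, dir) {
  labs <- as.character(imageLabels(dataset))
  paths <- character(nImages(dataset))
  for (i in seq_len(nImages(dataset))) {
    d <- file.path(dir, labs[i])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(d, sprintf("img%04d.png", i))
    writeImagePNG(dataset@images[[i]], paths[i])
  }
  invisible(paths)
}

#' Read a class-per-directory image tree
#'
#' @param dir directory with one subdirectory per class containing PNG/JPEG
#'   files; the class vocabulary is the sorted subdirectory names
#' @return a \linkS4class{LabeledImageSet}
#' @export
readClassSet <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L)
    stop("no class subdirectories found in ", dir, call. = FALSE)
  images <- list(); labels <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(dir, cl),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- readImageGray(f)
      labels <- c(labels, cl)
    }
  }
  labeledImageSet(images, labels, classes = classes)
}
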