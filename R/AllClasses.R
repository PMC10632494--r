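#' lungkit: contrast enhancement and small-CNN classification of chest images
#'
#' The package implements a contrast-enhancement operator for low-contrast
#' chest CT / X-ray images that weights every pixel by the Pochhammer
#' k-symbol of its global-histogram probability (a truncated k-symbol Lerch
#' transcendent form), quality-metric-driven selection of the fractional
#' exponent, a self-contained four-layer convolutional network classifier
#' with its training protocol (stratified holdout, five-fold
#' cross-validation, SGDM, early stopping, kernel-filter ablation), and
#' confusion-matrix evaluation metrics. Seeded synthetic generators provide
#' low-contrast phantoms and a separable three-class texture dataset so the
#' complete pipeline is exercisable without any external data.
#'
#' @useDynLib lungkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rpois sd
#' @include AllGenerics.R
#' @name lungkit-package
"_PACKAGE"

## ---------------------------------------------------------------------------
## Imaging classes
## ---------------------------------------------------------------------------

#' IntensityImage: a 2-D grid of integer-valued pixel intensities
#'
#' The canonical unit all operators transform: a grayscale image stored as a
#' numeric matrix (rows = image rows, columns = image columns) whose values
#' lie in \code{[0, depth - 1]}. Color inputs are reduced to luminance before
#' construction (see \code{\link{readImageGray}}).
#'
#' @slot pixels numeric matrix of intensities
#' @slot depth integer number of gray levels L (256 for 8-bit images)
#' @export
setClass("IntensityImage",
  representation(pixels = "matrix", depth = "integer"),
  prototype(pixels = matrix(0, 1, 1), depth = 256L))

setValidity("IntensityImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must have at least one row and one column")
  if (length(object@depth) != 1L || is.na(object@depth) || object@depth < 2L)
    return("depth must be a single integer >= 2")
  if (any(!is.finite(p))) return("all pixel values must be finite")
  if (any(p < 0) || any(p > object@depth - 1L))
    return(sprintf("pixel values must lie in [0, %d]", object@depth - 1L))
  TRUE
})

#' Construct an IntensityImage
#'
#' @param pixels numeric matrix of intensities in \code{[0, depth - 1]}
#' @param depth number of gray levels (default 256)
#' @return an \linkS4class{IntensityImage}
#' @examples
#' img <- intensityImage(matrix(c(10, 10, 20, 30), 2, 2, byrow = TRUE))
#' dim(pixels(img))
#' @export
intensityImage <- function(pixels, depth = 256L) {
  if (is.null(dim(pixels)) || length(dim(pixels)) != 2L)
    stop("pixels must be a 2-D matrix; got a non-matrix input", call. = FALSE)
  new("IntensityImage", pixels = pixels, depth = as.integer(depth))
}

#' @describeIn pixels pixel matrix of an IntensityImage
#' @param x object with pixel data
#' @return \code{pixels}: the numeric intensity matrix.
#' @name pixels
#' @export
setMethod("pixels", "IntensityImage", function(x) x@pixels)

#' @describeIn imageDepth gray-level count of an IntensityImage
#' @param x object with a gray-level depth
#' @return \code{imageDepth}: the integer number of gray levels.
#' @name imageDepth
#' @export
setMethod("imageDepth", "IntensityImage", function(x) x@depth)

setMethod("show", "IntensityImage", function(object) {
  p <- object@pixels
  cat(sprintf("IntensityImage %d x %d, depth %d, range [%g, %g]\n",
              nrow(p), ncol(p), object@depth, min(p), max(p)))
})

#' ProbabilityMap: per-pixel occurrence probabilities
#'
#' Entry (i, j) is the relative frequency of the intensity level at the same
#' position of the source image in the image's global histogram; this is the
#' base of the K-LTF enhancement weight. Summing one representative entry per
#' distinct intensity level gives exactly 1.
#'
#' @slot probs numeric matrix of probabilities in (0, 1]
#' @export
setClass("ProbabilityMap", representation(probs = "matrix"))

setValidity("ProbabilityMap", function(object) {
  p <- object@probs
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    return("all probabilities must be finite and in (0, 1]")
  TRUE
})

#' @describeIn pixels probability matrix of a ProbabilityMap
#' @export
setMethod("pixels", "ProbabilityMap", function(x) x@probs)

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap %d x %d, range (%g, %g]\n",
              nrow(object@probs), ncol(object@probs),
              min(object@probs), max(object@probs)))
})

#' KLTFParams: fractional parameters of the enhancement operator
#'
#' The per-pixel enhancement weight is
#' \deqn{w(p) = (p)_{N,k} / \alpha^{\beta}}
#' where \eqn{(p)_{N,k}} is the Pochhammer k-symbol of the pixel probability
#' \eqn{p}, \eqn{\alpha > 0} and \eqn{\beta \in (0,1)} are the fractional
#' parameters, \eqn{k > 0} the symbol step, and \eqn{N \ge 0} the truncation
#' order. Defaults \eqn{\alpha = 0.5}, \eqn{\beta = 0.11}, \eqn{k = 1},
#' \eqn{N = 1}.
#'
#' @slot alpha positive real
#' @slot beta real in (0, 1)
#' @slot k positive real symbol step
#' @slot order nonnegative integer truncation order N
#' @export
setClass("KLTFParams",
  representation(alpha = "numeric", beta = "numeric", k = "numeric", order = "integer"),
  prototype(alpha = 0.5, beta = 0.11, k = 1, order = 1L))

setValidity("KLTFParams", function(object) {
  if (length(object@alpha) != 1L || !is.finite(object@alpha) || object@alpha <= 0)
    return("alpha must be a single positive number")
  if (length(object@beta) != 1L || !is.finite(object@beta) ||
      object@beta <= 0 || object@beta >= 1)
    return("beta must be a single number strictly inside (0, 1)")
  if (length(object@k) != 1L || !is.finite(object@k) || object@k <= 0)
    return("k must be a single positive number")
  if (length(object@order) != 1L || is.na(object@order) || object@order < 0L)
    return("order must be a single nonnegative integer")
  TRUE
})

#' Construct K-LTF enhancement parameters
#'
#' @param alpha positive fractional parameter (default 0.5)
#' @param beta fractional exponent in (0, 1) (default 0.11)
#' @param k positive Pochhammer symbol step (default 1)
#' @param order nonnegative integer truncation order N (default 1)
#' @return a \linkS4class{KLTFParams} object
#' @export
kltfParams <- function(alpha = 0.5, beta = 0.11, k = 1, order = 1L) {
  new("KLTFParams", alpha = alpha, beta = beta, k = k, order = as.integer(order))
}

setMethod("show", "KLTFParams", function(object) {
  cat(sprintf("KLTFParams: alpha = %g, beta = %g, k = %g, order = %d\n",
              object@alpha, object@beta, object@k, object@order))
})

#' HistogramSummary: spread diagnostics of an intensity histogram
#'
#' Counts per gray level plus summary statistics used to diagnose contrast
#' stretching: mean, standard deviation, Shannon entropy in bits, the number
#' of occupied levels and the occupied-level range (max occupied minus min
#' occupied level).
#'
#' @slot counts integer vector of length \code{depth}
#' @slot mean,sd,entropy numeric scalars
#' @slot occupied integer count of levels with nonzero count
#' @slot levelRange integer spread between the extreme occupied levels
#' @export
setClass("HistogramSummary",
  representation(counts = "integer", mean = "numeric", sd = "numeric",
                 entropy = "numeric", occupied = "integer", levelRange = "integer"))

setMethod("show", "HistogramSummary", function(object) {
  cat(sprintf(paste0("HistogramSummary: %d levels occupied (range %d), mean %.2f, ",
                     "sd %.2f, entropy %.3f bits\n"),
              object@occupied, object@levelRange, object@mean, object@sd,
              object@entropy))
})

## ---------------------------------------------------------------------------
## Quality-selection classes
## ---------------------------------------------------------------------------

#' QualityScore: a no-reference image quality value
#'
#' All built-in metrics follow the blind-quality convention that a lower
#' value indicates better perceived quality, so grid selection always
#' minimizes.
#'
#' @slot metricName registered metric identifier
#' @slot value finite numeric score
#' @slot lowerIsBetter logical flag
#' @export
setClass("QualityScore",
  representation(metricName = "character", value = "numeric",
                 lowerIsBetter = "logical"))

setValidity("QualityScore", function(object) {
  if (!is.finite(object@value)) return("score value must be finite")
  TRUE
})

setMethod("show", "QualityScore", function(object) {
  cat(sprintf("QualityScore[%s] = %g (%s is better)\n", object@metricName,
              object@value, if (object@lowerIsBetter) "lower" else "higher"))
})

#' SweepResult: outcome of a beta grid sweep
#'
#' @slot grid ordered numeric vector of beta candidates
#' @slot averageScores mean quality score per candidate
#' @slot bestBeta candidate attaining the minimum average score (smallest
#'   beta on ties)
#' @slot perImageScores matrix, candidates x images
#' @slot metricName metric used for scoring
#' @export
setClass("SweepResult",
  representation(grid = "numeric", averageScores = "numeric",
                 bestBeta = "numeric", perImageScores = "matrix",
                 metricName = "character"))

setValidity("SweepResult", function(object) {
  if (length(object@grid) != length(object@averageScores))
    return("grid and averageScores lengths differ")
  if (nrow(object@perImageScores) != length(object@grid))
    return("perImageScores must have one row per grid candidate")
  mu <- rowMeans(object@perImageScores)
  if (max(abs(mu - object@averageScores)) > 1e-9)
    return("averageScores must equal the row means of perImageScores")
  m <- min(object@averageScores)
  winners <- object@grid[object@averageScores == m]
  if (abs(object@bestBeta - min(winners)) > 0)
    return("bestBeta must be the smallest beta attaining the minimum average score")
  TRUE
})

#' @describeIn bestBeta selected beta of a SweepResult
#' @param x a \linkS4class{SweepResult}
#' @return \code{bestBeta}: the selected beta value.
#' @name bestBeta
#' @export
setMethod("bestBeta", "SweepResult", function(x) x@bestBeta)

#' @describeIn averageScores per-candidate mean scores of a SweepResult
#' @param x a \linkS4class{SweepResult}
#' @return \code{averageScores}: named numeric vector of mean scores.
#' @name averageScores
#' @export
setMethod("averageScores", "SweepResult",
          function(x) structure(x@averageScores, names = format(x@grid)))

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult[%s]: %d candidates x %d images, best beta = %g\n",
              object@metricName, length(object@grid),
              ncol(object@perImageScores), object@bestBeta))
})

## ---------------------------------------------------------------------------
## Classifier classes
## ---------------------------------------------------------------------------

#' ArchitectureSpec: layer plan of the customized CNN
#'
#' The default specification is the published four-convolution plan:
#' 227 x 227 x 3 input, kernel 5, filter counts 16/32/64/128, each
#' convolution followed by batch normalization then ReLU, max pooling after
#' the first three blocks, then a fully connected softmax head over the
#' classes.
#'
#' @slot inputSize integer (height, width)
#' @slot inputChannels integer channel count
#' @slot convFilters ordered integer filter counts per convolution layer
#' @slot kernelSize integer spatial kernel extent
#' @slot poolLayers number of 2x2 max-pooling stages (after the leading blocks)
#' @slot numClasses output dimension
#' @export
setClass("ArchitectureSpec",
  representation(inputSize = "integer", inputChannels = "integer",
                 convFilters = "integer", kernelSize = "integer",
                 poolLayers = "integer", numClasses = "integer"))

setValidity("ArchitectureSpec", function(object) {
  if (length(object@inputSize) != 2L || any(object@inputSize < 1L))
    return("inputSize must be two positive integers (height, width)")
  if (object@inputChannels < 1L) return("inputChannels must be >= 1")
  if (length(object@convFilters) < 1L || any(object@convFilters < 1L))
    return("convFilters must be a nonempty vector of positive counts")
  if (object@kernelSize < 1L || object@kernelSize %% 2L != 1L)
    return("kernelSize must be a positive odd integer")
  if (object@poolLayers < 0L || object@poolLayers > length(object@convFilters))
    return("poolLayers must be between 0 and the number of conv layers")
  if (object@numClasses < 2L) return("numClasses must be >= 2")
  TRUE
})

#' Construct a CNN architecture specification
#'
#' @param inputSize image (height, width) fed to the network (default
#'   \code{c(227, 227)})
#' @param inputChannels input channel count (default 3)
#' @param convFilters filter counts per convolution layer (default
#'   \code{c(16, 32, 64, 128)})
#' @param kernelSize odd spatial kernel extent (default 5)
#' @param poolLayers number of max-pooling stages; default one fewer than the
#'   number of convolution layers
#' @param numClasses number of output classes (default 3)
#' @return an \linkS4class{ArchitectureSpec}
#' @examples
#' spec <- architectureSpec()
#' spec
#' @export
architectureSpec <- function(inputSize = c(227L, 227L), inputChannels = 3L,
                             convFilters = c(16L, 32L, 64L, 128L),
                             kernelSize = 5L,
                             poolLayers = length(convFilters) - 1L,
                             numClasses = 3L) {
  new("ArchitectureSpec", inputSize = as.integer(inputSize),
      inputChannels = as.integer(inputChannels),
      convFilters = as.integer(convFilters),
      kernelSize = as.integer(kernelSize), poolLayers = as.integer(poolLayers),
      numClasses = as.integer(numClasses))
}

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec: %dx%dx%d input, conv filters (%s) kernel %d, %d pools, %d classes\n",
              object@inputSize[1], object@inputSize[2], object@inputChannels,
              paste(object@convFilters, collapse = ", "), object@kernelSize,
              object@poolLayers, object@numClasses))
})

#' TrainingConfig: optimization and protocol hyperparameters
#'
#' Defaults follow the published training plan: SGDM with learning rate
#' 1e-4, momentum 0.9, batch size 32, at most 30 epochs, validation every 30
#' iterations with early stopping on validation loss, a stratified 30\%
#' holdout test split, and five-fold cross-validation.
#'
#' @slot learningRate,momentum,holdoutFraction numeric scalars
#' @slot batchSize,maxEpochs,validationFrequency,patience,cvFolds,seed integers
#' @slot optimizer identifier ("sgdm" is the only built-in)
#' @export
setClass("TrainingConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 maxEpochs = "integer", momentum = "numeric",
                 validationFrequency = "integer", patience = "integer",
                 seed = "integer", optimizer = "character",
                 holdoutFraction = "numeric", cvFolds = "integer"))

setValidity("TrainingConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@maxEpochs < 0L) return("maxEpochs must be >= 0")
  if (object@momentum < 0 || object@momentum >= 1)
    return("momentum must lie in [0, 1)")
  if (object@validationFrequency < 1L) return("validationFrequency must be >= 1")
  if (object@patience < 1L) return("patience must be >= 1")
  if (object@holdoutFraction <= 0 || object@holdoutFraction >= 1)
    return("holdoutFraction must lie strictly inside (0, 1)")
  if (object@cvFolds < 2L) return("cvFolds must be >= 2")
  if (!identical(object@optimizer, "sgdm"))
    return("optimizer must be 'sgdm'")
  TRUE
})

#' Construct a training configuration
#'
#' @param learningRate SGDM learning rate (default 1e-4)
#' @param batchSize mini-batch size (default 32)
#' @param maxEpochs maximum training epochs (default 30)
#' @param momentum SGDM momentum coefficient (default 0.9)
#' @param validationFrequency iterations between validation passes (default 30)
#' @param patience validation checks without loss improvement before early
#'   stop (default 5)
#' @param seed integer seed controlling initialization, shuffling, splits
#' @param optimizer optimizer identifier; only \code{"sgdm"} is built in
#' @param holdoutFraction test fraction of the stratified holdout (default 0.30)
#' @param cvFolds number of cross-validation folds (default 5)
#' @return a \linkS4class{TrainingConfig}
#' @export
trainingConfig <- function(learningRate = 1e-4, batchSize = 32L, maxEpochs = 30L,
                           momentum = 0.9, validationFrequency = 30L,
                           patience = 5L, seed = 0L, optimizer = "sgdm",
                           holdoutFraction = 0.30, cvFolds = 5L) {
  new("TrainingConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      momentum = momentum, validationFrequency = as.integer(validationFrequency),
      patience = as.integer(patience), seed = as.integer(seed),
      optimizer = optimizer, holdoutFraction = holdoutFraction,
      cvFolds = as.integer(cvFolds))
}

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf(paste0("TrainingConfig: %s lr %g, momentum %g, batch %d, <= %d epochs, ",
                     "val every %d iters (patience %d), holdout %.0f%%, %d folds, seed %d\n"),
              object@optimizer, object@learningRate, object@momentum,
              object@batchSize, object@maxEpochs, object@validationFrequency,
              object@patience, 100 * object@holdoutFraction, object@cvFolds,
              object@seed))
})

#' LabeledImageSet: images with class labels
#'
#' @slot images list of \linkS4class{IntensityImage} objects
#' @slot labels factor of class labels, one per image; the factor levels are
#'   the class vocabulary
#' @export
setClass("LabeledImageSet",
  representation(images = "list", labels = "factor"))

setValidity("LabeledImageSet", function(object) {
  if (length(object@images) != length(object@labels))
    return("images and labels must have the same length")
  if (any(is.na(object@labels)))
    return("labels must all belong to the class vocabulary (factor levels)")
  if (!all(vapply(object@images, is, logical(1), "IntensityImage")))
    return("all images must be IntensityImage objects")
  TRUE
})

#' Construct a labeled image set
#'
#' @param images list of \linkS4class{IntensityImage}
#' @param labels character or factor of class labels; the vocabulary defaults
#'   to the sorted unique labels
#' @param classes optional explicit class vocabulary
#' @return a \linkS4class{LabeledImageSet}
#' @export
labeledImageSet <- function(images, labels, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  labels <- factor(as.character(labels), levels = classes)
  if (length(labels) > 0L && any(table(labels) == 0L))
    stop("every class in the vocabulary needs at least one image", call. = FALSE)
  new("LabeledImageSet", images = images, labels = labels)
}

#' @describeIn nImages number of images in a LabeledImageSet
#' @param x a \linkS4class{LabeledImageSet}
#' @return \code{nImages}: integer image count.
#' @name nImages
#' @export
setMethod("nImages", "LabeledImageSet", function(x) length(x@images))

#' @describeIn imageLabels labels of a LabeledImageSet
#' @param x a \linkS4class{LabeledImageSet}
#' @return \code{imageLabels}: factor of class labels.
#' @name imageLabels
#' @export
setMethod("imageLabels", "LabeledImageSet", function(x) x@labels)

setMethod("show", "LabeledImageSet", function(object) {
  tab <- table(object@labels)
  cat(sprintf("LabeledImageSet: %d images, classes: %s\n", length(object@images),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
})

#' Subset a LabeledImageSet by image index
#'
#' Keeps the full class vocabulary (factor levels) even when a class drops
#' out of the subset, so downstream protocol checks can detect missing
#' classes explicitly.
#'
#' @param x a \linkS4class{LabeledImageSet}
#' @param i integer or logical index
#' @param j,...,drop ignored
#' @return a \linkS4class{LabeledImageSet}
#' @export
setMethod("[", "LabeledImageSet", function(x, i, j, ..., drop = FALSE) {
  new("LabeledImageSet", images = x@images[i],
      labels = factor(as.character(x@labels[i]), levels = levels(x@labels)))
})

#' TrainingHistory: per-iteration and per-validation-check training record
#'
#' @slot iterations data.frame with columns iteration, epoch, loss, accuracy
#'   (training mini-batch statistics)
#' @slot validation data.frame with columns iteration, loss, accuracy
#' @slot stopReason "max epochs" or "early stop"
#' @slot epochsCompleted integer
#' @export
setClass("TrainingHistory",
  representation(iterations = "data.frame", validation = "data.frame",
                 stopReason = "character", epochsCompleted = "integer"))

setValidity("TrainingHistory", function(object) {
  if (!object@stopReason %in% c("max epochs", "early stop"))
    return("stopReason must be 'max epochs' or 'early stop'")
  if (nrow(object@iterations) > 0L &&
      (any(object@iterations$accuracy < 0) || any(object@iterations$accuracy > 1)))
    return("training accuracies must lie in [0, 1]")
  if (nrow(object@validation) > 0L &&
      (any(object@validation$accuracy < 0) || any(object@validation$accuracy > 1)))
    return("validation accuracies must lie in [0, 1]")
  TRUE
})

setMethod("show", "TrainingHistory", function(object) {
  cat(sprintf("TrainingHistory: %d iterations over %d epochs, %d validation checks, stopped at %s\n",
              nrow(object@iterations), object@epochsCompleted,
              nrow(object@validation), object@stopReason))
})

#' CNNModel: a constructed (possibly trained) network
#'
#' Layer parameters live in \code{params}: one entry per convolution block
#' holding the kernel tensor (stored as a matrix of shape
#' filters x kernel^2 * channels), the per-filter bias, and the batch
#' normalization scale/shift with running statistics; plus the fully
#' connected weight and bias.
#'
#' @slot spec the \linkS4class{ArchitectureSpec} the model was built from
#' @slot params list of layer parameter lists
#' @slot classes character class vocabulary the output units map to
#' @slot trained logical
#' @export
setClass("CNNModel",
  representation(spec = "ArchitectureSpec", params = "list",
                 classes = "character", trained = "logical"),
  prototype(trained = FALSE))

setMethod("show", "CNNModel", function(object) {
  rep <- layerReport(object)
  cat(sprintf("CNNModel (%s): %d conv blocks, %d learnable tensors, %s\n",
              if (object@trained) "trained" else "initialized",
              length(object@spec@convFilters), nrow(rep),
              paste(object@classes, collapse = "/")))
})

## ---------------------------------------------------------------------------
## Evaluation classes
## ---------------------------------------------------------------------------

#' ConfusionCounts: one-vs-rest counts for a single class
#'
#' @slot className class identifier
#' @slot tp,fp,tn,fn nonnegative integer counts summing to the evaluated
#'   sample count
#' @export
setClass("ConfusionCounts",
  representation(className = "character", tp = "integer", fp = "integer",
                 tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  cts <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(is.na(cts)) || any(cts < 0L)) return("all counts must be nonnegative")
  TRUE
})

#' Construct one-vs-rest confusion counts
#'
#' @param tp,fp,tn,fn nonnegative integer counts
#' @param class optional class identifier
#' @return a \linkS4class{ConfusionCounts}
#' @export
confusionCounts <- function(tp, fp, tn, fn, class = "positive") {
  new("ConfusionCounts", className = class, tp = as.integer(tp),
      fp = as.integer(fp), tn = as.integer(tn), fn = as.integer(fn))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts[%s]: TP %d, FP %d, TN %d, FN %d\n",
              object@className, object@tp, object@fp, object@tn, object@fn))
})

#' EvaluationReport: confusion matrix with per-class and macro metrics
#'
#' Rows of the confusion matrix are true classes, columns predicted classes.
#' Per-class metrics are computed one-vs-rest; the macro value is the
#' unweighted mean across classes.
#'
#' @slot matrix classes x classes integer confusion matrix
#' @slot classes class vocabulary
#' @slot perClass data.frame: one row per class with columns class, tp, fp,
#'   tn, fn, accuracy, sensitivity, specificity, precision, f1, and logical
#'   degenerate flags
#' @slot macro named numeric: accuracy, sensitivity, specificity, precision, f1
#' @export
setClass("EvaluationReport",
  representation(matrix = "matrix", classes = "character",
                 perClass = "data.frame", macro = "numeric"))

setValidity("EvaluationReport", function(object) {
  if (nrow(object@matrix) != ncol(object@matrix))
    return("confusion matrix must be square")
  if (nrow(object@matrix) != length(object@classes))
    return("matrix dimension must match the class vocabulary")
  metr <- object@macro[c("accuracy", "sensitivity", "specificity", "precision", "f1")]
  if (any(is.na(metr)) || any(metr < 0) || any(metr > 1))
    return("macro metrics must lie in [0, 1]")
  TRUE
})

#' @describeIn macroMetrics macro-averaged metrics of an EvaluationReport
#' @param x an \linkS4class{EvaluationReport}
#' @return \code{macroMetrics}: named numeric vector.
#' @name macroMetrics
#' @export
setMethod("macroMetrics", "EvaluationReport", function(x) x@macro)

#' @describeIn perClassMetrics per-class metric table of an EvaluationReport
#' @param x an \linkS4class{EvaluationReport}
#' @return \code{perClassMetrics}: data.frame, one row per class.
#' @name perClassMetrics
#' @export
setMethod("perClassMetrics", "EvaluationReport", function(x) x@perClass)

#' @describeIn confusion confusion matrix of an EvaluationReport
#' @param x an \linkS4class{EvaluationReport}
#' @return \code{confusion}: integer matrix, rows = true, columns = predicted.
#' @name confusion
#' @export
setMethod("confusion", "EvaluationReport", function(x) x@matrix)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport over %d samples, %d classes\n",
              sum(object@matrix), length(object@classes)))
  cat(sprintf("  macro: acc %.4f, sens %.4f, spec %.4f, prec %.4f, F1 %.4f\n",
              object@macro["accuracy"], object@macro["sensitivity"],
              object@macro["specificity"], object@macro["precision"],
              object@macro["f1"]))
})
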