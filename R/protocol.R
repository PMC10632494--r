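#' @include cnn.R metrics.R
NULL

## seeded per-class index shuffling shared by split and folding
.shuffleByClass <- function(labels, seed) {
  withSeed(seed, {
    lapply(split(seq_along(labels), labels), function(ix)
      if (length(ix) > 1L) sample(ix) else ix)
  })
}

#' Stratified train/test holdout split
#'
#' Reserves a stratified test fraction (default 30\%) per class: each class
#' contributes \code{round(fraction * n_class)} test images (at least one,
#' never all), drawn by seeded shuffling, so the per-class test fraction is
#' within one image of the target. Deterministic for a fixed seed; train and
#' test are disjoint and jointly exhaustive.
#'
#' @param dataset a \linkS4class{LabeledImageSet} with at least two images
#'   per class
#' @param config a \linkS4class{TrainingConfig} supplying
#'   \code{holdoutFraction} and \code{seed}
#' @return list with \code{train} and \code{test}
#'   \linkS4class{LabeledImageSet}s
#' @export
splitHoldout <- function(dataset, config = trainingConfig()) {
  stopifnot(is(dataset, "LabeledImageSet"), is(config, "TrainingConfig"))
  tab <- table(imageLabels(dataset))
  if (any(tab < 2L))
    stop(sprintf("every class needs at least 2 images; offending: %s",
                 paste(names(tab)[tab < 2L], collapse = ", ")), call. = FALSE)
  byClass <- .shuffleByClass(imageLabels(dataset), config@seed)
  testIdx <- unlist(lapply(byClass, function(ix) {
    nTest <- min(max(round(config@holdoutFraction * length(ix)), 1L),
                 length(ix) - 1L)
    ix[seq_len(nTest)]
  }), use.names = FALSE)
  trainIdx <- setdiff(seq_len(nImages(dataset)), testIdx)
  list(train = dataset[sort(trainIdx)], test = dataset[sort(testIdx)])
}

#' Stratified k-fold assignment
#'
#' Internal to \code{\link{fiveFoldCV}} but exported for protocol testing:
#' returns a fold id per image such that every image sits in exactly one
#' fold and the folds are class-stratified (per class, fold sizes differ by
#' at most one). Deterministic for a fixed seed.
#'
#' @param labels factor of class labels
#' @param folds number of folds
#' @param seed integer seed
#' @return integer vector of fold ids in \code{1..folds}
#' @export
stratifiedFolds <- function(labels, folds, seed = 0L) {
  tab <- table(labels)
  if (any(tab < folds))
    stop(sprintf("every class needs at least %d images for %d folds; offending: %s",
                 folds, folds, paste(names(tab)[tab < folds], collapse = ", ")),
         call. = FALSE)
  byClass <- .shuffleByClass(labels, seed)
  fold <- integer(length(labels))
  for (ix in byClass)
    fold[ix] <- rep_len(seq_len(folds), length(ix))
  fold
}

## seeded down-sampling of every class to the minimum class count
.balanceClasses <- function(dataset, seed) {
  tab <- table(imageLabels(dataset))
  m <- min(tab)
  byClass <- .shuffleByClass(imageLabels(dataset), seed)
  keep <- sort(unlist(lapply(byClass, function(ix) ix[seq_len(m)]),
               use.names = FALSE))
  dataset[keep]
}

#' Five-fold (k-fold) cross-validation of the customized CNN
#'
#' Down-samples every class to the minimum class count (seeded), partitions
#' the balanced set into stratified folds, trains one model per fold on the
#' remaining folds, and evaluates on the held-out fold. The optional
#' \code{preprocess} hook (e.g. K-LTF enhancement) is applied to images only
#' after balancing and folding, so the partition is identical with and
#' without preprocessing under the same seed.
#'
#' @param dataset a \linkS4class{LabeledImageSet} with at least
#'   \code{cvFolds} images per class
#' @param spec an \linkS4class{ArchitectureSpec}; \code{numClasses} must
#'   match the vocabulary
#' @param config a \linkS4class{TrainingConfig}
#' @param preprocess optional function \code{IntensityImage ->
#'   IntensityImage} applied to every image before training/evaluation
#' @return list with \code{folds} (list of per-fold
#'   \linkS4class{EvaluationReport}), \code{mean} (named numeric mean of the
#'   macro metrics across folds), \code{pooled} (summed confusion matrix)
#'   and \code{foldAssignment}
#' @export
fiveFoldCV <- function(dataset, spec, config = trainingConfig(),
                       preprocess = NULL) {
  stopifnot(is(dataset, "LabeledImageSet"), is(spec, "ArchitectureSpec"))
  classes <- levels(imageLabels(dataset))
  if (spec@numClasses != length(classes))
    stop("spec numClasses must match the dataset class vocabulary", call. = FALSE)
  balanced <- .balanceClasses(dataset, config@seed)
  fold <- stratifiedFolds(imageLabels(balanced), config@cvFolds,
                          seed = config@seed + 1L)
  if (!is.null(preprocess))
    balanced@images <- lapply(balanced@images, preprocess)
  reports <- vector("list", config@cvFolds)
  for (f in seq_len(config@cvFolds)) {
    trainSet <- balanced[fold != f]
    testSet <- balanced[fold == f]
    model <- buildModel(spec, classes = classes, seed = config@seed + f)
    fit <- trainModel(model, trainSet, valSet = testSet, config = config)
    pred <- predictModel(fit$model, testSet)
    cm <- confusionMatrix(imageLabels(testSet), pred$labels, classes)
    reports[[f]] <- multiclassReport(cm, classes)
  }
  macro <- vapply(reports, macroMetrics, numeric(5))
  pooled <- Reduce(`+`, lapply(reports, confusion))
  list(folds = reports, mean = rowMeans(macro), pooled = pooled,
       foldAssignment = fold)
}

#' Kernel-filter ablation harness
#'
#' Trains and evaluates one model per filter configuration under an
#' identical stratified holdout split, seed and training configuration, so
#' only the convolution filter counts vary between rows. The default
#' configurations are the four published rows: (16,16,32,64),
#' (16,32,64,64), (16,32,32,128) and (16,32,64,128).
#'
#' @param dataset a \linkS4class{LabeledImageSet}
#' @param filterConfigs list of integer vectors of per-layer filter counts
#' @param config a \linkS4class{TrainingConfig}
#' @param baseSpec \linkS4class{ArchitectureSpec} supplying everything but
#'   the filter counts
#' @return data.frame with columns \code{configuration} (e.g.
#'   \code{"16-32-64-128"}) and \code{accuracy} (holdout macro accuracy in
#'   \code{[0, 1]}), ordered as given
#' @export
ablationRun <- function(dataset,
                        filterConfigs = list(c(16L, 16L, 32L, 64L),
                                             c(16L, 32L, 64L, 64L),
                                             c(16L, 32L, 32L, 128L),
                                             c(16L, 32L, 64L, 128L)),
                        config = trainingConfig(),
                        baseSpec = architectureSpec()) {
  stopifnot(is(dataset, "LabeledImageSet"))
  if (!is.list(filterConfigs) || length(filterConfigs) == 0L)
    stop("at least one filter configuration is required", call. = FALSE)
  for (fc in filterConfigs)
    if (length(fc) == 0L || any(!is.finite(fc)) || any(fc < 1) ||
        any(fc != floor(fc)))
      stop(sprintf("invalid filter tuple: (%s)", paste(fc, collapse = ", ")),
           call. = FALSE)
  classes <- levels(imageLabels(dataset))
  split <- splitHoldout(dataset, config)
  rows <- lapply(filterConfigs, function(fc) {
    spec <- architectureSpec(inputSize = baseSpec@inputSize,
                             inputChannels = baseSpec@inputChannels,
                             convFilters = as.integer(fc),
                             kernelSize = baseSpec@kernelSize,
                             poolLayers = min(baseSpec@poolLayers,
                                              length(fc) - 1L),
                             numClasses = length(classes))
    model <- buildModel(spec, classes = classes, seed = config@seed)
    fit <- trainModel(model, split$train, valSet = split$test, config = config)
    pred <- predictModel(fit$model, split$test)
    cm <- confusionMatrix(imageLabels(split$test), pred$labels, classes)
    data.frame(configuration = paste(fc, collapse = "-"),
               accuracy = unname(macroMetrics(multiclassReport(cm, classes))["accuracy"]))
  })
  do.call(rbind, rows)
}
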