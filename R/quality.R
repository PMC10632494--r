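#' @include kltf.R
NULL

## Registry of no-reference quality metrics. Each entry is a function
## (image, params) -> numeric, where params is the KLTFParams the image was
## enhanced with (NULL when scoring an unenhanced image); built-ins ignore
## params. All registered metrics follow the lower-is-better convention.
.qualityRegistry <- new.env(parent = emptyenv())

.registerBuiltins <- function() {
  assign("neg_entropy",
         function(image, params = NULL) -histogramSummary(image)@entropy,
         envir = .qualityRegistry)
  assign("neg_rms_contrast",
         function(image, params = NULL) -histogramSummary(image)@sd,
         envir = .qualityRegistry)
}

#' Register a no-reference quality metric
#'
#' Metrics drive the beta grid sweep (\code{\link{sweepBeta}}): the candidate
#' with the lowest corpus-average score is selected, following the
#' blind-quality convention that lower means better. An externally provided
#' BRISQUE implementation can be plugged in through this registry; the two
#' self-contained built-ins are \code{"neg_entropy"} (minus Shannon entropy
#' in bits, so maximal histogram spread wins) and \code{"neg_rms_contrast"}
#' (minus intensity standard deviation).
#'
#' @param name metric identifier
#' @param fn function \code{(image, params)} returning a finite numeric
#'   score; \code{params} is the \linkS4class{KLTFParams} used to produce
#'   the image (or NULL), so synthetic test metrics can depend on beta
#' @return invisibly, the metric name
#' @export
registerQualityMetric <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .qualityRegistry)
  invisible(name)
}

#' List registered quality metrics
#' @return character vector of metric names
#' @export
listQualityMetrics <- function() sort(ls(.qualityRegistry))

#' Score an image with a registered quality metric
#'
#' @param image an \linkS4class{IntensityImage}
#' @param metricName registered metric identifier
#' @param params optional \linkS4class{KLTFParams} the image was enhanced
#'   with, forwarded to the metric
#' @return a \linkS4class{QualityScore} (lower is better)
#' @examples
#' scoreImage(intensityImage(matrix(c(0, 0, 255, 255), 2, 2)), "neg_entropy")
#' @export
scoreImage <- function(image, metricName = "neg_entropy", params = NULL) {
  stopifnot(is(image, "IntensityImage"))
  if (!exists(metricName, envir = .qualityRegistry, inherits = FALSE))
    stop(sprintf("unknown quality metric '%s'; registered metrics: %s",
                 metricName, paste(listQualityMetrics(), collapse = ", ")),
         call. = FALSE)
  fn <- get(metricName, envir = .qualityRegistry)
  new("QualityScore", metricName = metricName,
      value = as.numeric(fn(image, params)), lowerIsBetter = TRUE)
}

#' Select the enhancement exponent beta by a quality-score grid sweep
#'
#' Reproduces the quality-driven parameter-selection methodology: every
#' corpus image is enhanced once per candidate beta (alpha, k and the
#' truncation order held fixed at \code{baseParams}), scored with the chosen
#' no-reference metric, and the candidate with the lowest mean score across
#' the corpus is selected. Ties go to the smallest beta. Deterministic for
#' fixed inputs.
#'
#' @param corpus list of \linkS4class{IntensityImage}
#' @param baseParams \linkS4class{KLTFParams} supplying alpha, k and order
#' @param grid ordered numeric vector of beta candidates, strictly inside
#'   (0, 1); default 0.01 to 0.99 in steps of 0.02
#' @param metricName registered quality metric (default \code{"neg_entropy"})
#' @return a \linkS4class{SweepResult}
#' @examples
#' imgs <- lapply(1:3, function(s) makePhantom(seed = s))
#' sw <- sweepBeta(imgs, grid = c(0.05, 0.11, 0.5))
#' bestBeta(sw)
#' @export
sweepBeta <- function(corpus, baseParams = kltfParams(),
                      grid = seq(0.01, 0.99, by = 0.02),
                      metricName = "neg_entropy") {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a nonempty list of IntensityImage objects", call. = FALSE)
  if (length(grid) == 0L)
    stop("beta grid must be nonempty", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid <= 0) || any(grid >= 1))
    stop("all beta candidates must lie strictly inside (0, 1)", call. = FALSE)
  stopifnot(is(baseParams, "KLTFParams"))

  scores <- matrix(NA_real_, length(grid), length(corpus))
  for (ci in seq_along(grid)) {
    pars <- kltfParams(alpha = baseParams@alpha, beta = grid[ci],
                       k = baseParams@k, order = baseParams@order)
    for (ii in seq_along(corpus)) {
      enh <- enhance(corpus[[ii]], pars)
      scores[ci, ii] <- scoreImage(enh, metricName, params = pars)@value
    }
  }
  avg <- rowMeans(scores)
  best <- min(grid[avg == min(avg)])          # smallest beta on ties
  new("SweepResult", grid = as.numeric(grid), averageScores = avg,
      bestBeta = best, perImageScores = scores, metricName = metricName)
}
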