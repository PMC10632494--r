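#' Enhance an image with the K-LTF operator
#'
#' Generic for the pixel-probability contrast-enhancement operator. See
#' \code{\link{enhance,IntensityImage-method}} for the implementation on
#' \linkS4class{IntensityImage}.
#'
#' @param x object to enhance
#' @param params a \linkS4class{KLTFParams} object
#' @param ... further arguments for methods
#' @return an object of the same class as \code{x}
#' @export
setGeneric("enhance", function(x, params = kltfParams(), ...) standardGeneric("enhance"))

#' @rdname pixels
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname imageDepth
#' @export
setGeneric("imageDepth", function(x) standardGeneric("imageDepth"))

#' @rdname histogramSummary
#' @export
setGeneric("histogramSummary", function(x) standardGeneric("histogramSummary"))

#' @rdname bestBeta
#' @export
setGeneric("bestBeta", function(x) standardGeneric("bestBeta"))

#' @rdname averageScores
#' @export
setGeneric("averageScores", function(x) standardGeneric("averageScores"))

#' @rdname macroMetrics
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' @rdname perClassMetrics
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname confusion
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname nImages
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname imageLabels
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))
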