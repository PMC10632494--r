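#' @include AllClasses.R AllGenerics.R
NULL

#' Per-pixel occurrence probabilities from the global histogram
#'
#' Computes, for every pixel, the relative frequency of its (integer) gray
#' level in the image's global histogram: \eqn{p(i,j) =}
#' count of pixels sharing level \eqn{I(i,j)} divided by the pixel count
#' \eqn{r \cdot q}. No smoothing and no locality: one 256-bin histogram of
#' the whole image (or \code{depth} bins when overridden).
#'
#' @param image an \linkS4class{IntensityImage}
#' @return a \linkS4class{ProbabilityMap} with the same shape
#' @examples
#' img <- intensityImage(matrix(c(10, 10, 20, 30), 2, 2, byrow = TRUE))
#' pixels(computeProbabilityMap(img))
#' @export
computeProbabilityMap <- function(image) {
  stopifnot(is(image, "IntensityImage"))
  validObject(image)
  px <- image@pixels
  lev <- as.integer(floor(px + 0.5))          # quantize to gray levels
  counts <- tabulate(lev + 1L, nbins = image@depth)
  p <- matrix(counts[lev + 1L] / length(lev), nrow(px), ncol(px))
  new("ProbabilityMap", probs = p)
}

#' Pochhammer k-symbol
#'
#' The n-term stepped product
#' \deqn{(p)_{n,k} = p (p + k)(p + 2k) \cdots (p + (n-1)k),}
#' with the empty product \eqn{(p)_{0,k} = 1}. At \eqn{k = 1} it reduces to
#' the classical rising factorial.
#'
#' @param p numeric base (vectorized)
#' @param n single nonnegative integer term count
#' @param k single positive step
#' @return numeric of the same length as \code{p}
#' @examples
#' pochhammerK(2, 3, 1)    # 2 * 3 * 4 = 24
#' pochhammerK(0.5, 2, 2)  # 0.5 * 2.5 = 1.25
#' @export
pochhammerK <- function(p, n, k = 1) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("n must be a single nonnegative integer", call. = FALSE)
  if (length(k) != 1L || !is.finite(k) || k <= 0)
    stop("k must be a single positive number", call. = FALSE)
  n <- as.integer(n)
  out <- rep(1, length(p))
  for (i in seq_len(n)) out <- out * (p + (i - 1L) * k)
  out
}

#' Finite partial sum of the k-symbol Lerch transcendent series
#'
#' Evaluates \eqn{\sum_{n=0}^{N} (p)_{n,k} / (\alpha + n)^{\beta}}, the
#' truncated series the enhancement operator derives from. Exposed for
#' testing and exploration only; the image operator uses the per-pixel
#' truncated form (see \code{\link{kltfWeight}}), not this series.
#'
#' @param p numeric base (vectorized)
#' @param alpha,beta series parameters, \code{alpha > 0}
#' @param k positive symbol step
#' @param nTerms number of terms minus one (sum runs n = 0..nTerms)
#' @return numeric partial sums
#' @export
lerchPartialSum <- function(p, alpha, beta, k = 1, nTerms = 10L) {
  stopifnot(alpha > 0, nTerms >= 0)
  out <- rep(0, length(p))
  for (n in 0:nTerms) out <- out + pochhammerK(p, n, k) / (alpha + n)^beta
  out
}

#' K-LTF enhancement weight of one pixel probability
#'
#' The multiplicative weight applied to a pixel of probability \eqn{p}:
#' \deqn{w(p) = (p)_{N,k} / \alpha^{\beta}.}
#' Strictly positive and nondecreasing in \eqn{p} for valid parameters.
#'
#' @param p probabilities in (0, 1] (vectorized)
#' @param params a \linkS4class{KLTFParams}
#' @return numeric weights
#' @examples
#' kltfWeight(0.5, kltfParams())  # 0.5 / 0.5^0.11
#' @export
kltfWeight <- function(p, params = kltfParams()) {
  stopifnot(is(params, "KLTFParams"))
  validObject(params)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("probabilities must be finite and strictly positive", call. = FALSE)
  pochhammerK(p, params@order, params@k) / params@alpha^params@beta
}

#' @describeIn enhance K-LTF contrast enhancement of an IntensityImage.
#'
#' Each pixel's raw enhanced value is
#' \eqn{I(i,j) \cdot (p(i,j))_{N,k} / \alpha^{\beta}} with \eqn{p(i,j)} the
#' global-histogram probability of its gray level; the raw image is then
#' min-max rescaled to \eqn{[0, L-1]} and rounded half-up. A flat input
#' (degenerate rescale) is returned unchanged.
#' @examples
#' img <- intensityImage(matrix(c(10, 10, 20, 30), 2, 2, byrow = TRUE))
#' pixels(enhance(img))  # [[0,0],[0,255]]
#' @export
setMethod("enhance", "IntensityImage", function(x, params = kltfParams(), ...) {
  validObject(x); validObject(params)
  p <- computeProbabilityMap(x)
  raw <- x@pixels * kltfWeight(p@probs, params)
  lo <- min(raw); hi <- max(raw)
  if (hi - lo <= 0) return(x)                 # flat raw output: identity
  scaled <- (raw - lo) / (hi - lo) * (x@depth - 1L)
  intensityImage(matrix(floor(scaled + 0.5), nrow(raw), ncol(raw)),
                 depth = x@depth)
})

#' @describeIn histogramSummary histogram-spread diagnostics of an image.
#'
#' Returns the gray-level counts together with the intensity mean, the
#' (sample) standard deviation, the Shannon entropy in bits of the
#' normalized histogram, the number of occupied levels, and the
#' occupied-level range (highest minus lowest occupied level) — the spread
#' statistics used to diagnose contrast stretching.
#' @examples
#' histogramSummary(intensityImage(matrix(c(0, 0, 255, 255), 2, 2)))
#' @export
setMethod("histogramSummary", "IntensityImage", function(x) {
  validObject(x)
  lev <- as.integer(floor(x@pixels + 0.5))
  counts <- tabulate(lev + 1L, nbins = x@depth)
  q <- counts[counts > 0] / length(lev)
  occ <- which(counts > 0L)
  new("HistogramSummary",
      counts = counts,
      mean = mean(x@pixels),
      sd = if (length(lev) > 1L) stats::sd(as.numeric(x@pixels)) else 0,
      entropy = -sum(q * log2(q)),
      occupied = length(occ),
      levelRange = as.integer(max(occ) - min(occ)))
})
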