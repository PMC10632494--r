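test_that("probability map equals per-level histogram frequencies", {
  # constant image: one occupied level, probability 1 everywhere
  const <- intensityImage(matrix(50, 8, 8))
  expect_equal(pixels(computeProbabilityMap(const)), matrix(1, 8, 8))

  # hand-counted 2x2 example: hist{10:2, 20:1, 30:1} / 4
  pm <- computeProbabilityMap(tinyImage())
  expect_equal(pixels(pm), matrix(c(0.5, 0.5, 0.25, 0.25), 2, 2, byrow = TRUE))

  # all-distinct intensities: every pixel at 1/n
  dist <- intensityImage(matrix(0:15, 4, 4))
  expect_equal(pixels(computeProbabilityMap(dist)), matrix(1 / 16, 4, 4))

  # shape preserved
  img <- makePhantom(shape = c(20, 33), seed = 4)
  expect_identical(dim(pixels(computeProbabilityMap(img))), c(20L, 33L))

  # degenerate inputs rejected at construction
  expect_error(intensityImage(numeric(0)), "matrix")
  expect_error(intensityImage(matrix(-1, 2, 2)), "pixel values")
})

test_that("probability conservation: one representative per level sums to 1", {
  for (seed in 1:5) {
    img <- makePhantom(seed = seed)
    p <- pixels(computeProbabilityMap(img))
    lev <- pixels(img)
    rep1 <- p[!duplicated(as.vector(lev))]
    expect_lt(abs(sum(rep1) - 1), 1e-12)
  }
})

test_that("Pochhammer k-symbol matches direct products and the loop oracle", {
  expect_identical(pochhammerK(0.7, 0, 5), 1)        # empty product
  expect_identical(pochhammerK(2, 3, 1), 24)         # 2*3*4
  expect_identical(pochhammerK(0.5, 2, 2), 1.25)     # 0.5*2.5
  expect_error(pochhammerK(1, -1, 1), "nonnegative")
  expect_error(pochhammerK(1, 1, 0), "positive")

  # loop-product oracle on 1000 random (p, n, k) triples
  set.seed(99)
  for (t in 1:1000) {
    p <- runif(1, 0.01, 3); n <- sample(0:8, 1); k <- runif(1, 0.1, 4)
    oracle <- 1
    for (i in seq_len(n)) oracle <- oracle * (p + (i - 1) * k)
    expect_lt(abs(pochhammerK(p, n, k) - oracle) / max(1e-300, abs(oracle)),
              1e-12)
  }

  # k = 1 reduces to the classical rising factorial p(p+1)...(p+n-1)
  for (p in 1:5) for (n in 0:5)
    expect_equal(pochhammerK(p, n, 1), prod(p + seq_len(n) - 1))
})

test_that("K-LTF weight matches scalar evaluations and is monotone in p", {
  # alpha = 1: denominator 1, single-term product = p
  expect_equal(kltfWeight(0.37, kltfParams(alpha = 1)), 0.37)
  # scalar evaluations at the published defaults (high-precision oracle)
  expect_equal(kltfWeight(0.5, kltfParams()), 0.5 / 0.5^0.11, tolerance = 1e-12)
  expect_equal(kltfWeight(0.5, kltfParams()), 0.539614, tolerance = 1e-6)
  expect_equal(kltfWeight(1, kltfParams(order = 2)), 2 / 0.5^0.11,
               tolerance = 1e-12)
  expect_equal(kltfWeight(1, kltfParams(order = 2)), 2.158456, tolerance = 1e-6)

  expect_error(kltfWeight(0, kltfParams()), "positive")
  expect_error(kltfWeight(-0.1, kltfParams()), "positive")

  # nondecreasing in p, strictly positive
  set.seed(7)
  for (t in 1:20) {
    pars <- kltfParams(alpha = runif(1, 0.1, 2), beta = runif(1, 0.01, 0.99),
                       k = runif(1, 0.2, 3), order = sample(0:4, 1))
    p <- sort(runif(50, 0.001, 1))
    w <- kltfWeight(p, pars)
    expect_true(all(w > 0))
    expect_true(all(diff(w) >= -1e-15))
  }
})

test_that("truncated Lerch partial sum accumulates the k-symbol terms", {
  # closed form at small order: sum_{n=0}^{2} (p)_{n,k} / (alpha+n)^beta
  p <- 0.4; a <- 0.5; b <- 0.3; k <- 1.5
  manual <- 1 / a^b + p / (a + 1)^b + p * (p + k) / (a + 2)^b
  expect_equal(lerchPartialSum(p, a, b, k, nTerms = 2), manual,
               tolerance = 1e-14)
})

test_that("enhance reproduces the worked 2x2 example bit-exactly", {
  out <- enhance(tinyImage(), kltfParams(alpha = 0.5, beta = 0.11, k = 1, order = 1))
  expect_identical(pixels(out), matrix(c(0, 0, 0, 255), 2, 2, byrow = TRUE))

  # and the raw (pre-rescale) values behind it
  w <- kltfWeight(c(0.5, 0.25, 0.25), kltfParams())
  raw <- c(10, 20, 30) * w
  expect_equal(raw, c(5.3961, 5.3961, 8.0941), tolerance = 1e-4)
})

test_that("enhance preserves shape, fixes flat images, spans full range", {
  const <- intensityImage(matrix(77, 5, 9))
  expect_identical(pixels(enhance(const)), pixels(const))  # flat fixed point

  for (seed in 1:5) {
    img <- makePhantom(shape = c(24, 40), seed = seed)
    out <- enhance(img)
    expect_identical(dim(pixels(out)), dim(pixels(img)))   # shape preserved
    expect_identical(range(pixels(out)), c(0, 255))        # min-max rescale
  }
})

test_that("enhancement stretches low-contrast phantom histograms", {
  # phantoms compressed into [100, 150]: sd and occupied-level range must
  # strictly increase (the stretched-histogram property)
  for (seed in 1:10) {
    img <- makePhantom(window = c(100, 150), seed = seed)
    hin <- histogramSummary(img)
    hout <- histogramSummary(enhance(img))
    expect_gt(hout@sd, hin@sd)
    expect_gt(hout@levelRange, hin@levelRange)
  }
})

test_that("histogram summary statistics match closed-form cases", {
  hconst <- histogramSummary(intensityImage(matrix(7, 4, 4)))
  expect_identical(hconst@entropy, 0)
  expect_identical(hconst@sd, 0)
  expect_identical(hconst@occupied, 1L)
  expect_identical(sum(hconst@counts), 16L)

  htwo <- histogramSummary(intensityImage(matrix(c(0, 0, 255, 255), 2, 2)))
  expect_equal(htwo@entropy, 1)           # two equiprobable levels -> 1 bit

  huni <- histogramSummary(intensityImage(matrix(rep(0:255, 4), 32, 32)))
  expect_equal(huni@entropy, 8)           # uniform over 256 levels -> 8 bits
})
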