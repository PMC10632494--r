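# Shared fixtures kept tiny: protocol and architecture tests do not need
# realistic image sizes.

tinyImage <- function() {
  intensityImage(matrix(c(10, 10, 20, 30), 2, 2, byrow = TRUE))
}

# a small spec that trains in well under a second per iteration
tinySpec <- function(classes = 3L) {
  architectureSpec(inputSize = c(16L, 16L), inputChannels = 1L,
                   convFilters = c(4L, 8L), kernelSize = 3L,
                   poolLayers = 1L, numClasses = classes)
}

tinyClassSet <- function(nPerClass = 5L, seed = 123L) {
  makeClassSet(nPerClass = nPerClass, imageSize = c(16L, 16L), seed = seed)
}

# deterministic non-flat test image covering many gray levels
rampImage <- function(rows = 16L, cols = 16L) {
  intensityImage(matrix(seq(0, 255, length.out = rows * cols) %/% 1, rows, cols))
}
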