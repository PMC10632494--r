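test_that("default architecture reproduces the published tensor plan", {
  spec <- architectureSpec()
  model <- buildModel(spec)
  shapes <- convWeightShapes(model)
  expect_identical(shapes, list(c(5L, 5L, 3L, 16L), c(5L, 5L, 16L, 32L),
                                c(5L, 5L, 32L, 64L), c(5L, 5L, 64L, 128L)))
  expect_identical(spec@inputSize, c(227L, 227L))
  expect_identical(spec@poolLayers, 3L)
  expect_identical(spec@numClasses, 3L)

  rep <- layerReport(model)
  convW <- rep[rep$tensor == "weights" & rep$layer != "fc", ]
  expect_identical(convW$shape, c("5 x 5 x 3 x 16", "5 x 5 x 16 x 32",
                                  "5 x 5 x 32 x 64", "5 x 5 x 64 x 128"))
  expect_equal(convW$count, c(1200, 12800, 51200, 204800), ignore_attr = TRUE)
  expect_equal(sum(convW$count), 270000)          # total conv weights
  biases <- rep[rep$tensor == "bias" & rep$layer != "fc", ]
  expect_identical(biases$shape, c("1 x 1 x 16", "1 x 1 x 32",
                                   "1 x 1 x 64", "1 x 1 x 128"))
  fcW <- rep[rep$layer == "fc" & rep$tensor == "weights", ]
  expect_match(fcW$shape, "^3 x ")                # 3 output units
})

test_that("filter-count chaining follows the ablation configuration rule", {
  spec <- architectureSpec(convFilters = c(16L, 16L, 32L, 64L))
  expect_identical(convWeightShapes(spec),
                   list(c(5L, 5L, 3L, 16L), c(5L, 5L, 16L, 16L),
                        c(5L, 5L, 16L, 32L), c(5L, 5L, 32L, 64L)))
})

test_that("too-small inputs are rejected naming the collapsing stage", {
  spec <- architectureSpec(inputSize = c(4L, 4L), convFilters = c(4L, 4L, 4L, 4L))
  expect_error(buildModel(spec), "pooling stage")
})

test_that("stratified holdout splits are exact, balanced and seeded", {
  ds <- tinyClassSet(nPerClass = 10)
  cfg <- trainingConfig(seed = 42)
  sp <- splitHoldout(ds, cfg)
  expect_equal(nImages(sp$test), 9L)              # 3 per class at 30%
  expect_equal(nImages(sp$train), 21L)
  expect_equal(unname(table(imageLabels(sp$test))), rep(3L, 3),
               ignore_attr = TRUE)

  # determinism and partition property
  sp2 <- splitHoldout(ds, cfg)
  expect_identical(imageLabels(sp$train), imageLabels(sp2$train))
  expect_identical(lapply(sp$test@images, pixels),
                   lapply(sp2$test@images, pixels))
  # different seeds give different draws (overwhelmingly likely)
  sp3 <- splitHoldout(ds, trainingConfig(seed = 43))
  expect_false(identical(lapply(sp$test@images, pixels),
                         lapply(sp3$test@images, pixels)))

  tiny <- ds[c(1, 11, 12, 21, 22)]                # one class with 1 image
  expect_error(splitHoldout(tiny, cfg), "at least 2")
})

test_that("stratified folds partition each class evenly", {
  ds <- tinyClassSet(nPerClass = 5)
  fold <- stratifiedFolds(imageLabels(ds), 5, seed = 1)
  expect_identical(sort(unique(fold)), 1:5)
  # each fold holds exactly one image per class
  for (f in 1:5)
    expect_equal(unname(table(imageLabels(ds)[fold == f])), rep(1L, 3),
                 ignore_attr = TRUE)
  # exact partition, deterministic
  expect_identical(fold, stratifiedFolds(imageLabels(ds), 5, seed = 1))
  expect_error(stratifiedFolds(imageLabels(tinyClassSet(nPerClass = 3)), 5),
               "at least 5")
})

test_that("backpropagation matches central-difference numerical gradients", {
  spec <- architectureSpec(inputSize = c(8L, 8L), inputChannels = 2L,
                           convFilters = c(2L, 3L), kernelSize = 3L,
                           poolLayers = 1L, numClasses = 2L)
  model <- buildModel(spec, seed = 7)
  set.seed(42)
  x <- array(rnorm(8 * 8 * 2 * 4), c(8, 8, 2, 4))
  y <- matrix(0, 2, 4); y[cbind(c(1, 2, 1, 2), 1:4)] <- 1
  fwd <- lungkit:::.forward(model, x, training = TRUE)
  gr <- lungkit:::.backward(model, fwd, y)
  lossAt <- function(m) {
    f <- lungkit:::.forward(m, x, training = TRUE)
    lungkit:::.crossEntropy(f$probs, y)
  }
  eps <- 1e-6
  probe <- function(getParam, setParam, analytic) {
    p <- getParam(model)
    for (i in sample(length(p), min(5L, length(p)))) {
      mp <- setParam(model, i, p[i] + eps)
      mm <- setParam(model, i, p[i] - eps)
      num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
      # mixed tolerance: the absolute floor covers null directions (conv
      # bias is absorbed by batch-norm mean subtraction, so its true
      # gradient is 0 and the central difference is pure roundoff noise)
      expect_lt(abs(num - analytic[i]),
                1e-6 + 1e-5 * (abs(num) + abs(analytic[i])))
    }
  }
  for (l in 1:2) for (nm in c("W", "b", "gamma", "beta")) {
    ana <- switch(nm, W = gr$conv[[l]]$dW, b = gr$conv[[l]]$db,
                  gamma = gr$conv[[l]]$dgamma, beta = gr$conv[[l]]$dbeta)
    probe(function(m) m@params$conv[[l]][[nm]],
          function(m, i, v) { m@params$conv[[l]][[nm]][i] <- v; m }, ana)
  }
  probe(function(m) m@params$fc$W,
        function(m, i, v) { m@params$fc$W[i] <- v; m }, gr$fc$dW)
})

test_that("training contracts: zero epochs, missing classes, determinism", {
  ds <- tinyClassSet(nPerClass = 4)
  spec <- tinySpec()
  model <- buildModel(spec, classes = levels(imageLabels(ds)), seed = 1)

  # max_epochs = 0: unchanged model, empty history, max-epochs stop
  fit0 <- trainModel(model, ds, config = trainingConfig(maxEpochs = 0, seed = 1))
  expect_identical(fit0$model@params, model@params)
  expect_false(fit0$model@trained)
  expect_equal(nrow(fit0$history@iterations), 0L)
  expect_identical(fit0$history@stopReason, "max epochs")

  # class absent from the training set is rejected
  sub <- ds[imageLabels(ds) != "normal"]
  expect_error(trainModel(model, sub, config = trainingConfig(maxEpochs = 1)),
               "normal")

  # same seed, same data -> identical trained parameters
  cfg <- trainingConfig(maxEpochs = 2, batchSize = 6, seed = 9)
  f1 <- trainModel(model, ds, config = cfg)
  f2 <- trainModel(model, ds, config = cfg)
  expect_identical(f1$model@params, f2$model@params)
  expect_identical(f1$history@iterations, f2$history@iterations)
})

test_that("early stopping halts after exactly the configured patience", {
  ds <- tinyClassSet(nPerClass = 4)
  spec <- tinySpec()
  model <- buildModel(spec, classes = levels(imageLabels(ds)), seed = 1)
  # constant validation loss stub; validate every iteration
  stub <- function(model, valSet) list(loss = 1.0, accuracy = 0.5)
  cfg <- trainingConfig(maxEpochs = 30, batchSize = 6, seed = 2,
                        validationFrequency = 1L, patience = 4L)
  fit <- trainModel(model, ds, valSet = ds, config = cfg,
                    validationEvaluator = stub)
  expect_identical(fit$history@stopReason, "early stop")
  expect_equal(nrow(fit$history@validation), 4L)
})

test_that("predictions are normalized with smallest-index tie-breaking", {
  ds <- tinyClassSet(nPerClass = 3)
  model <- buildModel(tinySpec(), classes = levels(imageLabels(ds)), seed = 3)
  pr <- predictModel(model, ds)
  expect_equal(rowSums(pr$probs), rep(1, nImages(ds)), tolerance = 1e-6)
  expect_true(all(pr$probs >= 0))
  expect_identical(levels(pr$labels), levels(imageLabels(ds)))

  # argmax / tie-break contract on explicit rows
  expect_equal(which.max(c(0.2, 0.5, 0.3)), 2L)
  expect_equal(which.max(c(0.5, 0.5, 0.0)), 1L)
})

test_that("five-fold CV partitions the balanced set and averages reports", {
  ds <- tinyClassSet(nPerClass = 6)     # imbalanced after dropping one image
  cfg <- trainingConfig(maxEpochs = 1, batchSize = 6, seed = 4, cvFolds = 5)
  cv <- fiveFoldCV(ds, tinySpec(), cfg)
  expect_length(cv$folds, 5L)
  # balanced down-sampling: 6 per class retained (already equal), folds
  # partition all 18 images
  expect_equal(length(cv$foldAssignment), 18L)
  expect_equal(sum(vapply(cv$folds, function(r) sum(confusion(r)), numeric(1))),
               18)
  expect_named(cv$mean, c("accuracy", "sensitivity", "specificity",
                          "precision", "f1"))
  expect_true(all(cv$mean >= 0 & cv$mean <= 1))
  # arithmetic-mean contract
  expect_equal(unname(cv$mean["f1"]),
               mean(vapply(cv$folds, function(r) macroMetrics(r)["f1"],
                           numeric(1))))
  # determinism
  cv2 <- fiveFoldCV(ds, tinySpec(), cfg)
  expect_identical(cv$foldAssignment, cv2$foldAssignment)
  expect_equal(cv$mean, cv2$mean)
})

test_that("the enhancement hook changes inputs but never the protocol", {
  ds <- tinyClassSet(nPerClass = 5)
  cfg <- trainingConfig(maxEpochs = 1, batchSize = 6, seed = 6, cvFolds = 5)
  plain <- fiveFoldCV(ds, tinySpec(), cfg)
  enhanced <- fiveFoldCV(ds, tinySpec(), cfg,
                         preprocess = function(img) enhance(img))
  expect_identical(plain$foldAssignment, enhanced$foldAssignment)
})

test_that("ablation tables are ordered, bounded and reject bad tuples", {
  ds <- tinyClassSet(nPerClass = 5)
  cfg <- trainingConfig(maxEpochs = 1, batchSize = 6, seed = 7)
  tab <- ablationRun(ds, filterConfigs = list(c(4L, 8L), c(2L, 4L)),
                     config = cfg, baseSpec = tinySpec())
  expect_equal(tab$configuration, c("4-8", "2-4"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_error(ablationRun(ds, filterConfigs = list(c(0L, 4L)), config = cfg,
                           baseSpec = tinySpec()),
               "invalid filter tuple")
  expect_error(ablationRun(ds, filterConfigs = list(), config = cfg),
               "at least one")
})
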