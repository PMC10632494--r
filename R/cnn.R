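#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Small-CNN engine: conv -> batch-norm -> ReLU (-> 2x2 max-pool) blocks,
## fully connected softmax head, SGDM training with early stopping.
## Convolutions are stride-1 same-padding (RcppArmadillo im2col kernels);
## pooling is 2x2 stride 2 with floor on odd extents.
## ---------------------------------------------------------------------------

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1   # EMA coefficient for running statistics

## run expr under a temporary seed without clobbering the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## spatial sizes after each block; errors if pooling collapses the map
.blockSizes <- function(spec) {
  h <- spec@inputSize[1]; w <- spec@inputSize[2]
  sizes <- vector("list", length(spec@convFilters))
  for (l in seq_along(spec@convFilters)) {
    if (l <= spec@poolLayers) { h <- h %/% 2L; w <- w %/% 2L }
    if (h < 1L || w < 1L)
      stop(sprintf("spatial size collapses to %dx%d after pooling stage %d; input too small for %d pool layers",
                   h, w, l, spec@poolLayers), call. = FALSE)
    sizes[[l]] <- c(h, w)
  }
  sizes
}

#' Build the customized CNN
#'
#' Constructs the network in the fixed block order: for every convolution
#' layer, conv (stride 1, same padding) then batch normalization then ReLU,
#' with a 2x2 max-pool after each of the first \code{poolLayers} blocks;
#' finally a fully connected layer to \code{numClasses} units with a softmax
#' output. Weights use seeded He (fan-in scaled) initialization; batch-norm
#' scale starts at 1, shift at 0.
#'
#' @param spec an \linkS4class{ArchitectureSpec}
#' @param classes class vocabulary; defaults to \code{class1..classK}
#' @param seed integer seed for weight initialization
#' @return a \linkS4class{CNNModel}; see \code{\link{layerReport}} for the
#'   learnable-tensor report
#' @examples
#' m <- buildModel(architectureSpec())
#' head(layerReport(m))
#' @export
buildModel <- function(spec, classes = NULL, seed = 0L) {
  stopifnot(is(spec, "ArchitectureSpec"))
  validObject(spec)
  sizes <- .blockSizes(spec)
  if (is.null(classes)) classes <- paste0("class", seq_len(spec@numClasses))
  if (length(classes) != spec@numClasses)
    stop("classes must have length numClasses", call. = FALSE)
  k <- spec@kernelSize
  withSeed(seed, {
    conv <- vector("list", length(spec@convFilters))
    cin <- spec@inputChannels
    for (l in seq_along(spec@convFilters)) {
      cout <- spec@convFilters[l]
      fanIn <- k * k * cin
      conv[[l]] <- list(
        W = matrix(rnorm(cout * fanIn, sd = sqrt(2 / fanIn)), cout, fanIn),
        b = numeric(cout),
        gamma = rep(1, cout), beta = numeric(cout),
        rmean = numeric(cout), rvar = rep(1, cout), bnSeen = FALSE,
        cin = cin)
      cin <- cout
    }
    last <- sizes[[length(sizes)]]
    D <- last[1] * last[2] * cin
    fc <- list(W = matrix(rnorm(spec@numClasses * D, sd = sqrt(2 / D)),
                          spec@numClasses, D),
               b = numeric(spec@numClasses))
    new("CNNModel", spec = spec, params = list(conv = conv, fc = fc),
        classes = as.character(classes), trained = FALSE)
  })
}

#' Learnable-tensor report of a CNN model
#'
#' One row per learnable tensor, in network order: convolution kernels
#' (height x width x in-channels x filters), per-filter biases
#' (1 x 1 x filters), batch-norm scale/shift, and the fully connected weight
#' and bias.
#'
#' @param model a \linkS4class{CNNModel}
#' @return data.frame with columns \code{layer}, \code{tensor}, \code{shape}
#'   (printed as \code{"a x b x ..."}) and \code{count}
#' @export
layerReport <- function(model) {
  stopifnot(is(model, "CNNModel"))
  spec <- model@spec
  k <- spec@kernelSize
  rows <- list()
  for (l in seq_along(spec@convFilters)) {
    cin <- model@params$conv[[l]]$cin
    cout <- spec@convFilters[l]
    nm <- paste0("conv", l)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = nm, tensor = "weights",
      shape = paste(c(k, k, cin, cout), collapse = " x "),
      count = k * k * cin * cout)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = nm, tensor = "bias", shape = paste(c(1, 1, cout), collapse = " x "),
      count = cout)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = nm, tensor = "bn_scale", shape = paste(c(1, 1, cout), collapse = " x "),
      count = cout)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = nm, tensor = "bn_shift", shape = paste(c(1, 1, cout), collapse = " x "),
      count = cout)
  }
  D <- ncol(model@params$fc$W)
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "fc", tensor = "weights",
    shape = paste(c(spec@numClasses, D), collapse = " x "),
    count = spec@numClasses * D)
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "fc", tensor = "bias", shape = paste(c(spec@numClasses, 1), collapse = " x "),
    count = spec@numClasses)
  do.call(rbind, rows)
}

#' Convolution kernel shapes of a model or spec
#'
#' @param x a \linkS4class{CNNModel} or \linkS4class{ArchitectureSpec}
#' @return list of integer vectors \code{(kernel, kernel, in, out)}, one per
#'   convolution layer
#' @export
convWeightShapes <- function(x) {
  spec <- if (is(x, "CNNModel")) x@spec else x
  k <- spec@kernelSize
  cin <- spec@inputChannels
  out <- vector("list", length(spec@convFilters))
  for (l in seq_along(spec@convFilters)) {
    out[[l]] <- as.integer(c(k, k, cin, spec@convFilters[l]))
    cin <- spec@convFilters[l]
  }
  out
}

## ----- input conversion ----------------------------------------------------

## one IntensityImage -> (H, W, C) array in [0, 1] at the spec's input size
.asInputArray <- function(img, spec) {
  px <- pixels(img) / (imageDepth(img) - 1L)
  th <- spec@inputSize[1]; tw <- spec@inputSize[2]
  if (nrow(px) != th || ncol(px) != tw) {
    # EBImage uses width-first layout; transpose in and out
    px <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(px)),
                                               w = tw, h = th)))
  }
  array(rep(px, spec@inputChannels), dim = c(th, tw, spec@inputChannels))
}

## list of IntensityImage -> (H, W, C, N) batch array
.asInputBatch <- function(images, spec) {
  arrs <- lapply(images, .asInputArray, spec = spec)
  out <- array(0, dim = c(spec@inputSize[1], spec@inputSize[2],
                          spec@inputChannels, length(arrs)))
  for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
  out
}

## ----- batch-norm helpers (channel = 3rd axis of (H,W,C,N) arrays) ---------

.toCh <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

.fromCh <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

.bnForwardTrain <- function(x, layer) {
  d <- dim(x)
  xm <- .toCh(x)
  mu <- colMeans(xm)
  va <- pmax(colMeans(xm * xm) - mu * mu, 0)
  invstd <- 1 / sqrt(va + .BN_EPS)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  if (!layer$bnSeen) { rmean <- mu; rvar <- va }
  else {
    rmean <- (1 - .BN_MOMENTUM) * layer$rmean + .BN_MOMENTUM * mu
    rvar <- (1 - .BN_MOMENTUM) * layer$rvar + .BN_MOMENTUM * va
  }
  list(y = .fromCh(y, d), xhat = xhat, invstd = invstd,
       rmean = rmean, rvar = rvar)
}

.bnForwardInfer <- function(x, layer) {
  d <- dim(x)
  xm <- .toCh(x)
  xhat <- sweep(sweep(xm, 2, layer$rmean), 2,
                1 / sqrt(layer$rvar + .BN_EPS), "*")
  .fromCh(sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+"), d)
}

.bnBackward <- function(dy, cache, gamma) {
  d <- dim(dy)
  dym <- .toCh(dy)
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$invstd, "*")
  list(dx = .fromCh(dx, d), dgamma = dgamma, dbeta = dbeta)
}

## ----- forward / backward --------------------------------------------------

.forward <- function(model, x, training = TRUE) {
  spec <- model@spec
  conv <- model@params$conv
  caches <- vector("list", length(conv))
  for (l in seq_along(conv)) {
    z <- conv2d_forward(x, conv[[l]]$W, conv[[l]]$b, spec@kernelSize)
    if (training) {
      bn <- .bnForwardTrain(z, conv[[l]])
      a <- bn$y
    } else {
      a <- .bnForwardInfer(z, conv[[l]])
      bn <- NULL
    }
    mask <- a > 0
    a <- a * mask
    if (l <= spec@poolLayers) {
      pooled <- maxpool2_forward(a)
      caches[[l]] <- list(x = x, bn = bn, mask = mask, adim = dim(a),
                          poolIdx = pooled$idx)
      x <- pooled$y
    } else {
      caches[[l]] <- list(x = x, bn = bn, mask = mask, adim = dim(a),
                          poolIdx = NULL)
      x <- a
    }
  }
  d <- dim(x)
  X <- matrix(x, nrow = prod(d[1:3]), ncol = d[4])
  logits <- model@params$fc$W %*% X + model@params$fc$b
  shifted <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(shifted)
  probs <- sweep(e, 2, colSums(e), "/")
  list(probs = probs, X = X, caches = caches, featDim = d)
}

## y: one-hot matrix (classes x N). Returns gradients for all tensors.
.backward <- function(model, fwd, y) {
  spec <- model@spec
  n <- ncol(y)
  dlogits <- (fwd$probs - y) / n
  grads <- list(fc = list(
    dW = dlogits %*% t(fwd$X),
    db = rowSums(dlogits)))
  dx <- array(t(model@params$fc$W) %*% dlogits, dim = fwd$featDim)
  convGrads <- vector("list", length(model@params$conv))
  for (l in rev(seq_along(model@params$conv))) {
    cache <- fwd$caches[[l]]
    if (!is.null(cache$poolIdx))
      dx <- maxpool2_backward(dx, cache$poolIdx, as.integer(cache$adim))
    dx <- dx * cache$mask
    bnb <- .bnBackward(dx, cache$bn, model@params$conv[[l]]$gamma)
    cb <- conv2d_backward(cache$x, model@params$conv[[l]]$W, bnb$dx,
                          spec@kernelSize)
    convGrads[[l]] <- list(dW = cb$dW, db = as.numeric(cb$db),
                           dgamma = bnb$dgamma, dbeta = bnb$dbeta)
    dx <- cb$dx
  }
  grads$conv <- convGrads
  grads
}

.crossEntropy <- function(probs, y) {
  -mean(log(pmax(colSums(probs * y), 1e-12)))
}

.oneHot <- function(labels, classes) {
  y <- matrix(0, length(classes), length(labels))
  y[cbind(match(as.character(labels), classes), seq_along(labels))] <- 1
  y
}

## zero-filled velocity structure matching the model parameters
.zeroVelocity <- function(model) {
  list(conv = lapply(model@params$conv, function(l)
         list(W = l$W * 0, b = l$b * 0, gamma = l$gamma * 0, beta = l$beta * 0)),
       fc = list(W = model@params$fc$W * 0, b = model@params$fc$b * 0))
}

## SGDM: v <- momentum * v - lr * g ; p <- p + v
.sgdmStep <- function(model, vel, grads, lr, momentum) {
  for (l in seq_along(model@params$conv)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      g <- switch(nm, W = grads$conv[[l]]$dW, b = grads$conv[[l]]$db,
                  gamma = grads$conv[[l]]$dgamma, beta = grads$conv[[l]]$dbeta)
      vel$conv[[l]][[nm]] <- momentum * vel$conv[[l]][[nm]] - lr * g
      model@params$conv[[l]][[nm]] <- model@params$conv[[l]][[nm]] + vel$conv[[l]][[nm]]
    }
  }
  vel$fc$W <- momentum * vel$fc$W - lr * grads$fc$dW
  vel$fc$b <- momentum * vel$fc$b - lr * grads$fc$db
  model@params$fc$W <- model@params$fc$W + vel$fc$W
  model@params$fc$b <- model@params$fc$b + vel$fc$b
  list(model = model, vel = vel)
}

## inference-mode loss/accuracy on a LabeledImageSet, in bounded chunks
.evaluateSet <- function(model, dataset, chunk = 32L) {
  n <- nImages(dataset)
  labs <- as.character(imageLabels(dataset))
  loss <- 0; correct <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    x <- .asInputBatch(dataset@images[idx], model@spec)
    fwd <- .forward(model, x, training = FALSE)
    y <- .oneHot(labs[idx], model@classes)
    loss <- loss + .crossEntropy(fwd$probs, y) * length(idx)
    pred <- apply(fwd$probs, 2, which.max)
    correct <- correct + sum(model@classes[pred] == labs[idx])
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Train a CNN with SGDM and early stopping
#'
#' Runs mini-batch stochastic gradient descent with momentum under the
#' configured learning rate, batch size and epoch budget. Batch
#' normalization uses batch statistics during training and exponentially
#' averaged running statistics at inference. Every
#' \code{validationFrequency} iterations the validation set (when given) is
#' scored; training stops early once \code{patience} consecutive validation
#' checks have passed without a strict decrease in validation loss (the
#' first check establishes the baseline). Fully reproducible for a fixed
#' seed.
#'
#' @param model an initialized \linkS4class{CNNModel}
#' @param trainSet a \linkS4class{LabeledImageSet}; every model class must
#'   be present
#' @param valSet optional validation \linkS4class{LabeledImageSet}
#' @param config a \linkS4class{TrainingConfig}
#' @param validationEvaluator optional function \code{(model, valSet)}
#'   returning \code{list(loss =, accuracy =)}; replaces the built-in
#'   inference-mode evaluation (used e.g. to inject evaluation stubs)
#' @return list with elements \code{model} (trained \linkS4class{CNNModel})
#'   and \code{history} (\linkS4class{TrainingHistory})
#' @export
trainModel <- function(model, trainSet, valSet = NULL, config = trainingConfig(),
                       validationEvaluator = NULL) {
  stopifnot(is(model, "CNNModel"), is(trainSet, "LabeledImageSet"),
            is(config, "TrainingConfig"))
  validObject(config)
  labs <- as.character(imageLabels(trainSet))
  missing <- setdiff(model@classes, unique(labs))
  if (length(missing) > 0L)
    stop(sprintf("class(es) absent from the training set: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  n <- nImages(trainSet)
  doVal <- !is.null(valSet) || !is.null(validationEvaluator)
  evalFun <- if (!is.null(validationEvaluator)) validationEvaluator
             else function(m, v) .evaluateSet(m, v)

  iterRows <- list(); valRows <- list()
  stopReason <- "max epochs"; epochsDone <- 0L
  withSeed(config@seed, {
    vel <- .zeroVelocity(model)
    iter <- 0L; bestLoss <- Inf; badChecks <- 0L; halted <- FALSE
    for (epoch in seq_len(config@maxEpochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config@batchSize)
      for (s in starts) {
        idx <- perm[s:min(s + config@batchSize - 1L, n)]
        x <- .asInputBatch(trainSet@images[idx], model@spec)
        y <- .oneHot(labs[idx], model@classes)
        fwd <- .forward(model, x, training = TRUE)
        # commit batch-norm running statistics
        for (l in seq_along(model@params$conv)) {
          model@params$conv[[l]]$rmean <- fwd$caches[[l]]$bn$rmean
          model@params$conv[[l]]$rvar <- fwd$caches[[l]]$bn$rvar
          model@params$conv[[l]]$bnSeen <- TRUE
        }
        loss <- .crossEntropy(fwd$probs, y)
        pred <- apply(fwd$probs, 2, which.max)
        acc <- mean(model@classes[pred] == labs[idx])
        grads <- .backward(model, fwd, y)
        upd <- .sgdmStep(model, vel, grads, config@learningRate, config@momentum)
        model <- upd$model; vel <- upd$vel
        iter <- iter + 1L
        iterRows[[iter]] <- data.frame(iteration = iter, epoch = epoch,
                                       loss = loss, accuracy = acc)
        if (doVal && iter %% config@validationFrequency == 0L) {
          ev <- evalFun(model, valSet)
          valRows[[length(valRows) + 1L]] <-
            data.frame(iteration = iter, loss = ev$loss, accuracy = ev$accuracy)
          if (is.finite(bestLoss) && ev$loss < bestLoss) {
            bestLoss <- ev$loss; badChecks <- 0L
          } else {
            if (!is.finite(bestLoss)) bestLoss <- ev$loss   # baseline check
            badChecks <- badChecks + 1L
          }
          if (badChecks >= config@patience) {
            stopReason <- "early stop"; halted <- TRUE; break
          }
        }
      }
      epochsDone <- epoch
      if (halted) break
    }
  })
  model@trained <- TRUE
  emptyIter <- data.frame(iteration = integer(), epoch = integer(),
                          loss = numeric(), accuracy = numeric())
  emptyVal <- data.frame(iteration = integer(), loss = numeric(),
                         accuracy = numeric())
  history <- new("TrainingHistory",
                 iterations = if (length(iterRows)) do.call(rbind, iterRows) else emptyIter,
                 validation = if (length(valRows)) do.call(rbind, valRows) else emptyVal,
                 stopReason = stopReason, epochsCompleted = epochsDone)
  if (config@maxEpochs == 0L) model@trained <- FALSE
  list(model = model, history = history)
}

#' Predict class labels and probabilities
#'
#' Runs the network in inference mode (batch normalization uses running
#' statistics). Images are resized bilinearly to the spec input size and
#' grayscale inputs replicated across channels. The predicted label is the
#' argmax of the softmax row; exact ties go to the smallest class index.
#'
#' @param model a \linkS4class{CNNModel}
#' @param images a \linkS4class{LabeledImageSet} or list of
#'   \linkS4class{IntensityImage}
#' @return list with \code{labels} (factor over the model classes) and
#'   \code{probs} (images x classes matrix; rows sum to 1)
#' @export
predictModel <- function(model, images) {
  stopifnot(is(model, "CNNModel"))
  imgs <- if (is(images, "LabeledImageSet")) images@images else images
  if (length(imgs) == 0L) stop("no images to predict", call. = FALSE)
  probs <- matrix(NA_real_, length(imgs), length(model@classes),
                  dimnames = list(NULL, model@classes))
  for (start in seq(1L, length(imgs), by = 32L)) {
    idx <- start:min(start + 31L, length(imgs))
    x <- .asInputBatch(imgs[idx], model@spec)
    fwd <- .forward(model, x, training = FALSE)
    probs[idx, ] <- t(fwd$probs)
  }
  pred <- apply(probs, 1, which.max)   # first max = smallest class index
  list(labels = factor(model@classes[pred], levels = model@classes),
       probs = probs)
}
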