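#' Architecture summary of the action-image classifier
#'
#' The classifier is a small convolutional network tailored to the
#' 15 x 32 x 3 action images: three pairs of stacked 3 x 3 convolutions
#' (64, 64, 128, 128, 256, 256 filters; padding 1, stride 1), each
#' convolution followed by batch normalization and ReLU; 2 x 2 max-pooling
#' after conv 2 and conv 4 (the feature-map width follows 32 -> 16 -> 8,
#' the odd height 15 -> 7 -> 3 with floor semantics); global average
#' pooling after conv 6; and a single fully connected softmax head. Global
#' average pooling keeps the head parameter-free over space, which both
#' counteracts overfitting and enables class activation maps.
#'
#' @param nClasses number of output classes.
#' @return data.frame with one row per layer: \code{layer}, \code{type},
#'   \code{filters}, \code{height}, \code{width} (output shape).
#' @export
modelSpec <- function(nClasses = 9L) {
  data.frame(
    layer = c("conv1", "conv2", "pool1", "conv3", "conv4", "pool2",
              "conv5", "conv6", "gap", "fc"),
    type = c("conv", "conv", "maxpool", "conv", "conv", "maxpool",
             "conv", "conv", "gap", "fc"),
    filters = c(64L, 64L, 64L, 128L, 128L, 128L, 256L, 256L, 256L,
                as.integer(nClasses)),
    height = c(15L, 15L, 7L, 7L, 7L, 3L, 3L, 3L, 1L, 1L),
    width = c(32L, 32L, 16L, 16L, 16L, 8L, 8L, 8L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Build an untrained action-image classifier
#'
#' Initializes the network of [modelSpec()] with He-uniform convolution
#' weights (seeded), unit batch-norm scales and zero biases.
#'
#' @param nClasses number of classes (>= 2).
#' @param seed seed for weight initialization.
#' @param classes optional label vocabulary of length \code{nClasses};
#'   defaults to placeholder names until the model is trained.
#' @param zeroFC if \code{TRUE} the fully connected head is zero-initialized
#'   (useful to verify the symmetric, uniform-probability starting point).
#' @return an untrained [TrainedModel-class].
#' @export
buildModel <- function(nClasses, seed = 1L, classes = NULL, zeroFC = FALSE) {
  if (nClasses < 2) stop("nClasses must be >= 2")
  if (is.null(classes)) classes <- sprintf("class%d", seq_len(nClasses))
  stopifnot(length(classes) == nClasses)
  params <- .cnn_init(as.integer(nClasses), as.integer(seed), zeroFC)
  new("TrainedModel", params = params, classes = as.character(classes),
      orderingId = NA_character_,
      history = data.frame(epoch = integer(), loss = numeric(),
                           accuracy = numeric()),
      seed = as.integer(seed), config = list())
}

#' Training configuration
#'
#' Defaults follow the full training protocol: 200 epochs of SGD
#' (momentum 0.9) with batch size 64, initial learning rate 0.01 reduced by
#' a factor of ten every 50 epochs, L2 weight decay 1e-4, repeated over 20
#' runs for the statistics.
#'
#' @param epochs training epochs.
#' @param batchSize mini-batch size.
#' @param lr initial learning rate.
#' @param lrStepEvery epochs between learning-rate reductions.
#' @param lrFactor multiplicative reduction factor.
#' @param momentum SGD momentum.
#' @param weightDecay L2 penalty on convolution and head weights.
#' @param runs number of repeated training runs in experiments.
#' @return a list of class \code{TrainingConfig}.
#' @export
trainingConfig <- function(epochs = 200L, batchSize = 64L, lr = 0.01,
                           lrStepEvery = 50L, lrFactor = 0.1,
                           momentum = 0.9, weightDecay = 1e-4, runs = 20L) {
  stopifnot(epochs >= 1, batchSize >= 1, lr > 0, lrStepEvery >= 1,
            lrFactor > 0, momentum >= 0, weightDecay >= 0, runs >= 1)
  cfg <- list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
              lr = lr, lrStepEvery = as.integer(lrStepEvery),
              lrFactor = lrFactor, momentum = momentum,
              weightDecay = weightDecay, runs = as.integer(runs))
  class(cfg) <- "TrainingConfig"
  cfg
}

#' Learning rate in effect at a given epoch
#'
#' @param config a [trainingConfig()].
#' @param epoch 1-based epoch number.
#' @return the step-schedule learning rate, e.g. 0.01 for epochs 1--50 and
#'   0.001 from epoch 51 under the defaults.
#' @export
learningRateAt <- function(config, epoch) {
  config$lr * config$lrFactor^((epoch - 1) %/% config$lrStepEvery)
}

# Stack a list of ActionImages into the [1440 x N] input matrix the network
# consumes (integer image rescaled by 1/255 at the boundary).
.imagesToMatrix <- function(images) {
  x <- vapply(images, function(im) as.numeric(pixels(im)) / 255,
              numeric(15 * 32 * 3))
  matrix(x, nrow = 15 * 32 * 3)
}

.checkSingleOrdering <- function(images) {
  ids <- unique(vapply(images, orderingId, ""))
  if (length(ids) > 1L)
    stop(sprintf(
      "images encoded under different orderings must never be mixed (%s)",
      paste(ids, collapse = ", ")))
  ids
}

#' Train the action-image classifier
#'
#' Fits the network of [modelSpec()] on a dataset of encoded action images
#' with mini-batch SGD under the step learning-rate schedule of
#' \code{config}. All images must share one joint ordering; the trained
#' model remembers it and refuses inputs encoded differently. Training is
#' deterministic given \code{seed} (single-threaded, seeded initialization
#' and shuffling).
#'
#' @param train a [LabeledDataset-class] of [ActionImage-class] samples.
#' @param config a [trainingConfig()].
#' @param seed seed for initialization and batch shuffling.
#' @param model optional pre-built [TrainedModel-class] to continue from;
#'   by default a fresh model is initialized from \code{seed}.
#' @return a [TrainedModel-class] with per-epoch history.
#' @export
trainModel <- function(train, config = trainingConfig(), seed = 1L,
                       model = NULL) {
  if (length(train) == 0L) stop("training dataset is empty")
  if (!is(train[[1]], "ActionImage"))
    stop("training dataset must contain encoded ActionImages; see encodeDataset()")
  ordId <- .checkSingleOrdering(train@samples)
  classes <- classVocabulary(train)
  y <- match(classLabel(train), classes) - 1L
  X <- .imagesToMatrix(train@samples)
  if (is.null(model))
    model <- buildModel(length(classes), seed = seed, classes = classes)
  fit <- .cnn_train(model@params, X, as.integer(y),
                    config$epochs, config$batchSize, config$lr,
                    config$lrStepEvery, config$lrFactor, config$momentum,
                    config$weightDecay, as.integer(seed))
  new("TrainedModel", params = fit$params, classes = classes,
      orderingId = ordId,
      history = data.frame(epoch = seq_len(config$epochs),
                           loss = fit$loss, accuracy = fit$accuracy),
      seed = as.integer(seed), config = unclass(config))
}

.checkImageOrdering <- function(model, images) {
  if (!is.na(model@orderingId)) {
    ids <- unique(vapply(images, orderingId, ""))
    if (any(ids != model@orderingId))
      stop(sprintf(
        "image ordering (%s) does not match the model's training ordering (%s)",
        paste(setdiff(ids, model@orderingId), collapse = ", "),
        model@orderingId))
  }
}

#' Classify one action image
#'
#' @param model a [TrainedModel-class].
#' @param image an [ActionImage-class] whose ordering matches the model's.
#' @return list with \code{probabilities} (named, summing to 1),
#'   \code{label} (argmax, ties broken by lowest class index) and
#'   \code{score} (the top softmax probability).
#' @export
predictAction <- function(model, image) {
  stopifnot(is(image, "ActionImage"))
  .checkImageOrdering(model, list(image))
  probs <- drop(.cnn_forward(model@params, .imagesToMatrix(list(image)))$probs)
  names(probs) <- model@classes
  k <- which.max(probs)
  list(probabilities = probs, label = model@classes[k],
       score = unname(probs[k]))
}

#' Classify a batch of action images
#'
#' @param model a [TrainedModel-class].
#' @param images list of [ActionImage-class] objects, or a
#'   [LabeledDataset-class] of images.
#' @return numeric matrix of class probabilities, one row per image,
#'   columns named by class.
#' @export
predictBatch <- function(model, images) {
  if (is(images, "LabeledDataset")) images <- images@samples
  .checkImageOrdering(model, images)
  probs <- .cnn_forward(model@params, .imagesToMatrix(images))$probs
  colnames(probs) <- model@classes
  probs
}

#' @describeIn predictAction \code{predict} method for trained models;
#'   dispatches to [predictBatch()] for lists/datasets and to
#'   [predictAction()] for a single image.
#' @param object a [TrainedModel-class].
#' @param newdata image(s) to classify.
#' @param ... ignored.
#' @export
setMethod("predict", "TrainedModel", function(object, newdata, ...) {
  if (is(newdata, "ActionImage")) predictAction(object, newdata)
  else predictBatch(object, newdata)
})
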