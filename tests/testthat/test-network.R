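test_that("the layer census matches the architecture contract", {
  spec <- modelSpec(9)
  expect_identical(sum(spec$type == "conv"), 6L)
  expect_identical(sum(spec$type == "maxpool"), 2L)
  expect_identical(sum(spec$type == "fc"), 1L)
  expect_identical(spec$filters[spec$type == "conv"],
                   c(64L, 64L, 128L, 128L, 256L, 256L))
  # feature-map width chain 32 -> 16 -> 8; height 15 -> 7 -> 3
  expect_identical(unique(spec$width[spec$type %in% c("conv", "maxpool")]),
                   c(32L, 16L, 8L))
  expect_identical(spec$width[spec$layer == "conv6"], 8L)
  expect_identical(spec$height[spec$layer == "conv6"], 3L)
})

test_that("built models have the right parameter shapes and output width", {
  m <- buildModel(9, seed = 1)
  expect_identical(dim(m@params$W1), c(27L, 64L))    # 3 channels x 3 x 3
  expect_identical(dim(m@params$W6), c(2304L, 256L))
  expect_identical(dim(m@params$Wfc), c(256L, 9L))
  expect_length(m@params$g4, 128L)
  m5 <- buildModel(5, seed = 1)
  expect_identical(dim(m5@params$Wfc), c(256L, 5L))
  expect_error(buildModel(1), ">= 2")
})

test_that("forward passes yield probabilities and 3 x 8 pre-GAP maps", {
  m <- buildModel(9, seed = 3)
  img <- encodeSequence(randomSequence(32, seed = 5))
  out <- predictAction(m, img)
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-6)
  expect_length(out$probabilities, 9L)
  expect_identical(out$label, names(which.max(out$probabilities)))
  fm <- skelact:::.cnn_forward(m@params,
                               skelact:::.imagesToMatrix(list(img)),
                               want_fmaps = TRUE)$fmaps
  expect_identical(dim(array(fm[, 1], c(3, 8, 256)))[1:2], c(3L, 8L))
  expect_identical(nrow(fm), 3L * 8L * 256L)
})

test_that("a zero-initialized head predicts the uniform distribution", {
  m <- buildModel(9, seed = 2, zeroFC = TRUE)
  img <- encodeSequence(randomSequence(32, seed = 6))
  out <- predictAction(m, img)
  expect_equal(unname(out$probabilities), rep(1 / 9, 9), tolerance = 1e-6)
})

test_that("the learning-rate schedule steps down by a factor of ten", {
  cfg <- trainingConfig()
  expect_identical(cfg$epochs, 200L)
  expect_identical(cfg$batchSize, 64L)
  expect_equal(cfg$weightDecay, 1e-4)
  expect_identical(cfg$runs, 20L)
  expect_equal(learningRateAt(cfg, 1), 0.01)
  expect_equal(learningRateAt(cfg, 50), 0.01)
  expect_equal(learningRateAt(cfg, 51), 0.001)
  expect_equal(learningRateAt(cfg, 101), 1e-4)
})

test_that("a small network memorizes a tiny training set", {
  model <- tinyTrainedModel()   # 45 images, 12 epochs, no weight decay
  expect_equal(utils::tail(model@history$accuracy, 1), 100)
  # training loss is non-increasing on a moving-average scale
  ma <- stats::filter(model@history$loss, rep(1 / 4, 4), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) < 0.05))
  # memorized images are predicted correctly in eval mode
  imgs <- tinyTrainImages()
  probs <- predictBatch(model, imgs)
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  expect_identical(pred, classLabel(imgs))
})

test_that("training is deterministic given the seed", {
  imgs <- tinyTrainImages()[1:18]
  cfg <- trainingConfig(epochs = 4, runs = 1)
  m1 <- trainModel(imgs, cfg, seed = 31)
  m2 <- trainModel(imgs, cfg, seed = 31)
  expect_equal(m1@history$loss, m2@history$loss, tolerance = 1e-7)
  expect_equal(m1@params$Wfc, m2@params$Wfc, tolerance = 1e-7)
  m3 <- trainModel(imgs, cfg, seed = 32)
  expect_false(isTRUE(all.equal(m1@params$Wfc, m3@params$Wfc)))
})

test_that("images from different orderings are never mixed", {
  s <- randomSequence(32, seed = 8)
  imgB <- encodeSequence(s, "B1")
  imgC <- encodeSequence(s, "C2")
  mixed <- new("LabeledDataset", samples = list(imgB, imgC),
               label = c("IDLE", "IDLE"), subject = c("S01", "S01"),
               viewpoint = c("front", "front"), classes = actionClasses())
  expect_error(trainModel(mixed, trainingConfig(epochs = 1, runs = 1)),
               "never be mixed")
  model <- tinyTrainedModel()   # trained under B1
  expect_error(predictAction(model, imgC), "does not match")
  expect_error(predictBatch(model, list(imgC)), "does not match")
})
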