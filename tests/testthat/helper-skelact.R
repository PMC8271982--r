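# Shared fixtures and independent oracles for the test suite.

# Random skeleton sequence with strictly positive coordinate range per axis.
randomSequence <- function(n = 32L, seed = 1L, spread = 1) {
  withr::with_seed(seed, {
    coords <- array(stats::runif(15 * 3 * n, -spread, spread),
                    dim = c(15L, 3L, n))
    SkeletonSequence(coords, subject = "S99", label = "IDLE",
                     viewpoint = "front", sampleId = sprintf("rand%d", seed))
  })
}

# Naive per-pixel encoder: triple loop over rows, frames and channels,
# applying the min-max normalization one scalar at a time.
naiveEncode <- function(coords, ordSeq) {
  J <- dim(coords)[1]; n <- dim(coords)[3]
  out <- array(0L, dim = c(J, n, 3L))
  for (a in 1:3) {
    cmin <- min(coords[, a, ]); cmax <- max(coords[, a, ])
    for (r in seq_len(J)) {
      j <- ordSeq[r]
      for (f in seq_len(n)) {
        if (cmax > cmin) {
          v <- 255 * (coords[j, a, f] - cmin) / (cmax - cmin)
          out[r, f, a] <- as.integer(floor(v + 0.5))
        }
      }
    }
  }
  out
}

# Sample-level multiclass Matthews correlation: expands the confusion matrix
# into label vectors and correlates the one-hot indicator matrices.
mccFromIndicators <- function(cm) {
  K <- nrow(cm)
  true <- rep(rep(seq_len(K), K), times = as.vector(t(cm)))
  pred <- rep(rep(seq_len(K), each = K), times = as.vector(t(cm)))
  Tm <- outer(true, seq_len(K), "==") * 1
  Pm <- outer(pred, seq_len(K), "==") * 1
  covs <- function(a, b) sum(diag(crossprod(scale(a, scale = FALSE),
                                            scale(b, scale = FALSE))))
  den <- sqrt(covs(Tm, Tm) * covs(Pm, Pm))
  if (den == 0) 0 else covs(Tm, Pm) / den
}

# Minimal dataset mirroring the protocol layout (1-frame sequences) for
# split bookkeeping tests that do not need real kinematics.
mockDataset <- function(nSubjects) {
  vps <- c("front", "front", "front", "left", "right")
  grid <- expand.grid(rep = 1:5, class = actionClasses(),
                      subject = seq_len(nSubjects),
                      stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(grid)), function(i)
    SkeletonSequence(array(stats::runif(45), c(15, 3, 1)),
                     subject = sprintf("S%02d", grid$subject[i]),
                     label = grid$class[i], viewpoint = vps[grid$rep[i]]))
  new("LabeledDataset", samples = samples, label = grid$class,
      subject = sprintf("S%02d", grid$subject),
      viewpoint = vps[grid$rep], classes = actionClasses())
}

# Memoized tiny trained model (one noiseless subject, all 9 classes) shared
# by the prediction, CAM and stream tests.
.fixtures <- new.env(parent = emptyenv())

tinyTrainedModel <- function() {
  if (is.null(.fixtures$model)) {
    proto <- collectionProtocol(nSubjects = 1, sigma = 0, seed = 5)
    ds <- generateDataset(proto)
    imgs <- encodeDataset(ds, "B1")
    .fixtures$trainImages <- imgs
    .fixtures$model <- trainModel(
      imgs, trainingConfig(epochs = 40, batchSize = 16, weightDecay = 0,
                           runs = 1),
      seed = 2)
    .fixtures$subject <- sampleSubject(1, 5, sigma = 0)
  }
  .fixtures$model
}

tinySubject <- function() { tinyTrainedModel(); .fixtures$subject }
tinyTrainImages <- function() { tinyTrainedModel(); .fixtures$trainImages }
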