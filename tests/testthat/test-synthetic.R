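test_that("subject parameters are deterministic and subject-specific", {
  a <- sampleSubject(3, 42)
  b <- sampleSubject(3, 42)
  expect_identical(a, b)
  subj <- lapply(1:32, sampleSubject, seed = 42)
  scales <- vapply(subj, function(s) s$scale, 0)
  expect_true(all(scales >= 0.7 & scales <= 1.1))
  # 32 draws are pairwise distinct parameter sets
  for (i in 1:31) for (j in (i + 1):32)
    expect_false(identical(subj[[i]][-1], subj[[j]][-1]),
                 label = sprintf("subjects %d vs %d", i, j))
  expect_identical(sampleSubject(1, 1, sigma = 0)$sigma, 0)
  expect_error(sampleSubject(1, 1, sigma = 0.5), "sigma")
})

test_that("a motionless noiseless subject produces identical frames", {
  s <- sampleSubject(1, 7, sigma = 0)
  s$ampMult <- 0
  s$postureOffset[] <- 0
  seq <- generateAction("IDLE", s, nFrames = 40, seed = 1)
  co <- jointCoords(seq)
  for (f in 2:40)
    expect_equal(co[, , f], co[, , 1], tolerance = 1e-12)
})

test_that("generated actions are deterministic given the same seed", {
  s <- sampleSubject(2, 7)
  a <- generateAction("CLAP", s, "left", nFrames = 48, seed = 9)
  b <- generateAction("CLAP", s, "left", nFrames = 48, seed = 9)
  expect_identical(jointCoords(a), jointCoords(b))
  c <- generateAction("CLAP", s, "left", nFrames = 48, seed = 10)
  expect_false(identical(jointCoords(a), jointCoords(c)))
})

test_that("hand waving moves the wrist but not the hips", {
  s <- sampleSubject(4, 11, sigma = 0)
  seq <- generateAction("HAND_WAVE", s, nFrames = 64, seed = 1)
  co <- jointCoords(seq)
  wristVar <- stats::var(co[9, 1, ]) + stats::var(co[9, 2, ])
  hipVar <- stats::var(co[13, 1, ]) + stats::var(co[13, 2, ])
  expect_gt(wristVar, hipVar)
  expect_equal(hipVar, 0, tolerance = 1e-20)
  for (f in 2:64)
    expect_equal(co[10:15, , f], co[10:15, , 1], tolerance = 1e-12)
})

test_that("unknown classes and viewpoints are rejected", {
  s <- sampleSubject(1, 1)
  expect_error(generateAction("JUMPING", s), "unknown action class")
  expect_error(generateAction("IDLE", s, viewpoint = "back"), "viewpoint")
  expect_error(generateAction("IDLE", s, nFrames = 16), ">= 32")
})

test_that("bone lengths stay constant within noiseless sequences", {
  edges <- skeletonEdges()
  s <- sampleSubject(6, 13, sigma = 0)
  for (cls in actionClasses()) {
    seq <- generateAction(cls, s, sample(c("front", "left", "right"), 1),
                          nFrames = 48, seed = 2)
    co <- jointCoords(seq)
    for (e in seq_len(nrow(edges))) {
      d <- sqrt(colSums((co[edges[e, 1], , ] - co[edges[e, 2], , ])^2))
      expect_lt(max(d) - min(d), 1e-9,
                label = sprintf("%s bone %d-%d", cls, edges[e, 1],
                                edges[e, 2]))
    }
  }
})

test_that("every generated frame passes the skeleton invariants", {
  ds <- generateDataset(collectionProtocol(nSubjects = 2, seed = 21))
  for (i in seq_len(length(ds)))
    expect_s4_class(validateSequence(ds[[i]]), "SkeletonSequence")
})

test_that("the protocol enumerates subjects, classes and viewpoints", {
  proto <- collectionProtocol(nSubjects = 1, seed = 2)
  ds <- generateDataset(proto)
  expect_identical(length(ds), 45L)        # 1 subject x 9 classes x 5
  expect_identical(as.vector(table(classLabel(ds))), rep(5L, 9L))
  expect_identical(sort(unique(viewpoint(ds))),
                   c("front", "left", "right"))
  expect_identical(as.vector(table(viewpoint(ds)))[1], 27L)  # 3 of 5 frontal
  man <- generateManifest(proto)
  expect_identical(nrow(man), 45L)
  expect_identical(man$sample_id, vapply(ds@samples, sampleId, ""))
  expect_true(all(man$seed >= 0 & man$seed < 2^31))
})

test_that("dataset generation is bit-reproducible from the master seed", {
  p <- collectionProtocol(nSubjects = 2, nFrames = 36, seed = 77)
  d1 <- generateDataset(p)
  d2 <- generateDataset(p)
  expect_identical(lapply(d1@samples, jointCoords),
                   lapply(d2@samples, jointCoords))
  d3 <- generateDataset(collectionProtocol(nSubjects = 2, nFrames = 36,
                                           seed = 78))
  expect_false(identical(jointCoords(d1[[1]]), jointCoords(d3[[1]])))
})

test_that("classes separate at the encoding level for noiseless subjects", {
  ds <- generateDataset(collectionProtocol(nSubjects = 3, sigma = 0,
                                           seed = 31))
  imgs <- encodeDataset(ds, "B1")
  # compare within one viewpoint: camera placement, not class identity,
  # dominates the raw image distance otherwise
  imgs <- imgs[viewpoint(imgs) == "front"]
  cls <- classLabel(imgs)
  avg <- lapply(actionClasses(), function(k) {
    sel <- which(cls == k)
    Reduce(`+`, lapply(sel, function(i) pixels(imgs[[i]]) / 255)) /
      length(sel)
  })
  names(avg) <- actionClasses()
  within <- mean(vapply(seq_len(length(imgs)), function(i)
    mean(abs(pixels(imgs[[i]]) / 255 - avg[[cls[i]]])), 0))
  between <- c()
  for (i in seq_along(avg)) for (j in seq_along(avg))
    if (i < j) between <- c(between, mean(abs(avg[[i]] - avg[[j]])))
  expect_gt(min(between), within)
})
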