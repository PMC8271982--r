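test_that("every registered ordering is a permutation of the 15 joints", {
  for (id in registeredOrderings()) {
    ord <- getOrdering(id)
    expect_identical(sort(orderingSequence(ord)), 1:15, label = id)
  }
})

test_that("registered orderings match their defining tables", {
  expect_identical(orderingSequence(getOrdering("B1")),
                   c(4L, 5L, 6L, 7L, 8L, 9L, 1L, 2L, 3L, 10L, 11L, 12L,
                     13L, 14L, 15L))
  expect_identical(orderingSequence(getOrdering("C2")),
                   c(5L, 13L, 11L, 8L, 3L, 6L, 2L, 9L, 15L, 10L, 7L, 12L,
                     1L, 4L, 14L))
  # B6 reverses the group order (right leg, left leg, torso, right arm,
  # left arm), expanded through the group membership
  expect_identical(orderingSequence(getOrdering("B6")),
                   c(13L, 14L, 15L, 10L, 11L, 12L, 1L, 2L, 3L, 7L, 8L, 9L,
                     4L, 5L, 6L))
})

test_that("B-configurations are group-contiguous", {
  groups <- jointGroups()
  for (id in paste0("B", 1:6)) {
    s <- orderingSequence(getOrdering(id))
    for (k in 0:4) {
      triple <- s[(3 * k + 1):(3 * k + 3)]
      hit <- vapply(groups, identical, TRUE, y = as.integer(triple))
      expect_true(any(hit), label = sprintf("%s positions %d-%d", id,
                                            3 * k + 1, 3 * k + 3))
    }
  }
  expect_true(all(vapply(jointGroups(), length, 0L) == 3L))
  expect_identical(sort(unlist(jointGroups(), use.names = FALSE)), 1:15)
})

test_that("unknown ordering ids are rejected with the registry listed", {
  err <- expect_error(getOrdering("C9"), "unknown ordering")
  expect_match(conditionMessage(err), "B1")
  expect_match(conditionMessage(err), "C5")
  expect_error(jointOrdering("bad", c(1:14, 14L)), "permutation")
})

test_that("selectJoints keeps the 15 canonical joints and drops extras", {
  withr::with_seed(4, {
    raw <- matrix(rnorm(19 * 3), 19, 3)
    rownames(raw) <- c(jointNames(), "left hand", "right hand",
                       "left foot", "right foot")
  })
  frame <- selectJoints(raw)
  expect_identical(dim(frame), c(15L, 3L))
  expect_identical(rownames(frame), jointNames())
  expect_equal(unname(frame), unname(raw[1:15, ]))
  # idempotent on its own output, and identity on an exact 15-joint frame
  expect_identical(selectJoints(frame), frame)
  # tolerant of name formatting
  raw2 <- raw
  rownames(raw2)[4] <- "Left_Shoulder"
  expect_equal(selectJoints(raw2), frame)
})

test_that("selectJoints reports missing and non-finite joints by name", {
  raw <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(jointNames(), NULL))
  err <- expect_error(selectJoints(raw[-6, ]), "missing joint")
  expect_match(conditionMessage(err), "left wrist")
  raw[9, 2] <- NaN
  err2 <- expect_error(selectJoints(raw), "non-finite")
  expect_match(conditionMessage(err2), "right wrist")
})

test_that("validateSequence passes valid input through and names bad frames", {
  s <- randomSequence(32)
  expect_identical(validateSequence(s), s)
  bad <- jointCoords(s)
  bad[3, 3, 7] <- NaN
  s2 <- SkeletonSequence(bad)
  err <- expect_error(validateSequence(s2), "frame 7")
  expect_match(conditionMessage(err), "torso")
  expect_error(SkeletonSequence(list()), "N must be >= 1")
})

test_that("skeleton CSV and JSONL round-trip coordinates and metadata", {
  ds <- generateDataset(collectionProtocol(nSubjects = 1, nFrames = 34,
                                           seed = 3))
  ds <- ds[1:4]
  man <- data.frame(sample_id = vapply(ds@samples, sampleId, ""),
                    subject = subjectId(ds), class = classLabel(ds),
                    viewpoint = viewpoint(ds), stringsAsFactors = FALSE)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeSkeletonCSV(ds, csv)
  back <- readSkeletonCSV(csv, manifest = man)
  expect_identical(length(back), 4L)
  expect_identical(classLabel(back), classLabel(ds))
  expect_identical(subjectId(back), subjectId(ds))
  expect_equal(jointCoords(back[[2]]), jointCoords(ds[[2]]),
               tolerance = 1e-9)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeSkeletonJSONL(ds[[1]], jl)
  seq2 <- readSkeletonJSONL(jl)
  expect_equal(unname(jointCoords(seq2)), unname(jointCoords(ds[[1]])),
               tolerance = 1e-9)
})

test_that("KARD files are remapped onto the canonical numbering", {
  # one frame whose value encodes the KARD slot: joint k has coords (k, k, k)
  kard <- withr::local_tempfile(fileext = ".txt")
  writeLines(apply(matrix(rep(1:15, each = 3), 3), 2, paste,
                   collapse = " "), kard)
  s <- readKARD(kard)
  expect_identical(nFrames(s), 1L)
  co <- jointCoords(s)
  # KARD order: head neck torso, right arm (hand->wrist), left arm,
  # right leg (foot->ankle), left leg
  expect_equal(co["head", "x", 1], 1)
  expect_equal(co["right shoulder", "x", 1], 4)
  expect_equal(co["right wrist", "x", 1], 6)    # right hand -> wrist slot
  expect_equal(co["left wrist", "x", 1], 9)     # left hand -> wrist slot
  expect_equal(co["right ankle", "x", 1], 12)   # right foot -> ankle slot
  expect_equal(co["left hip", "x", 1], 13)
  short <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 2 3", short)
  expect_error(readKARD(short), "15 joints")
})
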