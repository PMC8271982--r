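test_that("normalizeCoordinate implements the min-max map to 0-255", {
  expect_equal(normalizeCoordinate(0, 0, 10), 0)
  expect_equal(normalizeCoordinate(10, 0, 10), 255)
  expect_equal(normalizeCoordinate(4, 0, 10), 102)
  expect_equal(normalizeCoordinate(c(0, 5, 10), 0, 10), c(0, 127.5, 255))
  expect_warning(out <- normalizeCoordinate(3, 3, 3), "degenerate")
  expect_equal(out, 0)
  expect_error(normalizeCoordinate(NaN, 0, 1), "non-finite")
  expect_error(normalizeCoordinate(1, 2, 1), "cmax")
})

test_that("the encoding kernel matches hand-computed toy pixels", {
  # joint A pinned at the origin, joint B moving (1,2,3) -> (2,4,6)
  coords <- array(0, dim = c(2, 3, 2))
  coords[2, , 1] <- c(1, 2, 3)
  coords[2, , 2] <- c(2, 4, 6)
  pix <- skelact:::.encodeCoords(coords, 1:2)
  for (a in 1:3) {
    expect_identical(pix[1, , a], c(0L, 0L))          # A at the axis minimum
    expect_identical(pix[2, , a], c(128L, 255L))      # 127.5 rounds half-up
  }
})

test_that("encodeSequence produces a well-formed 15 x 32 x 3 image", {
  s <- randomSequence(32, seed = 7)
  img <- encodeSequence(s, "B1")
  expect_s4_class(img, "ActionImage")
  expect_identical(dim(pixels(img)), c(15L, 32L, 3L))
  expect_true(all(pixels(img) >= 0L & pixels(img) <= 255L))
  expect_identical(orderingId(img), "B1")
  expect_identical(sampleId(img), sampleId(s))
  expect_identical(img@windowStart, 0L)
  # both normalization extremes are attained on a non-degenerate sequence
  expect_identical(max(pixels(img)), 255L)
  expect_identical(min(pixels(img)), 0L)
})

test_that("sequences of the wrong length are directed to the windowing API", {
  err <- expect_error(encodeSequence(randomSequence(31, seed = 1)), "31")
  expect_match(conditionMessage(err), "slidingWindows")
  expect_error(encodeSequence(randomSequence(33, seed = 1)), "exactly 32")
})

test_that("a constant axis yields an all-zero channel with a warning", {
  s <- randomSequence(32, seed = 2)
  co <- jointCoords(s)
  co[, 1, ] <- 0.5
  expect_warning(img <- encodeSequence(SkeletonSequence(co)), "degenerate")
  expect_true(all(pixels(img)[, , 1] == 0L))
  expect_true(any(pixels(img)[, , 2] > 0L))
})

test_that("sliding windows have the documented count, length and starts", {
  s64 <- randomSequence(64, seed = 3)
  w1 <- slidingWindows(s64, 32, 1)
  expect_length(w1, 33L)
  expect_identical(vapply(w1, nFrames, 0L), rep(32L, 33L))
  expect_identical(w1[[1]]@startFrame, 0L)
  expect_identical(w1[[33]]@startFrame, 32L)
  w32 <- slidingWindows(s64, 32, 32)
  expect_length(w32, 2L)
  expect_identical(vapply(w32, function(w) w@startFrame, 0L), c(0L, 32L))
  expect_equal(jointCoords(w32[[2]]), jointCoords(s64)[, , 33:64],
               ignore_attr = TRUE)
  expect_message(w0 <- slidingWindows(randomSequence(31, seed = 3), 32),
                 "shorter")
  expect_length(w0, 0L)
})

test_that("encoding under two orderings differs only by the row permutation", {
  ords <- c("B1", "B4", "C2", "C3")
  for (seed in 1:5) {
    s <- randomSequence(32, seed = seed)
    imgs <- lapply(ords, function(o) pixels(encodeSequence(s, o)))
    for (i in seq_along(ords)) {
      for (j in seq_along(ords)) {
        oi <- orderingSequence(getOrdering(ords[i]))
        oj <- orderingSequence(getOrdering(ords[j]))
        expect_identical(imgs[[j]], imgs[[i]][match(oj, oi), , ,
                                              drop = FALSE],
                         label = sprintf("%s vs %s seed %d", ords[i],
                                         ords[j], seed))
      }
    }
  }
})

test_that("encodings are invariant to per-axis translation and scaling", {
  for (seed in 1:5) {
    s <- randomSequence(32, seed = seed)
    ref <- pixels(encodeSequence(s))
    co <- jointCoords(s)
    co[, 1, ] <- co[, 1, ] + 3.7          # translate x
    co[, 2, ] <- co[, 2, ] * 12.5         # scale y
    co[, 3, ] <- co[, 3, ] * 0.04 - 9.1   # both on z
    expect_identical(pixels(encodeSequence(SkeletonSequence(co))), ref)
  }
})

test_that("the vectorized encoder matches the naive per-pixel oracle", {
  for (seed in 1:25) {
    s <- randomSequence(32, seed = 100 + seed)
    ord <- getOrdering(sample(registeredOrderings(), 1))
    expect_identical(unname(pixels(encodeSequence(s, ord))),
                     naiveEncode(jointCoords(s), orderingSequence(ord)),
                     label = sprintf("seed %d ordering %s", seed,
                                     orderingId(ord)))
  }
})

test_that("action images survive a PNG + sidecar round trip", {
  img <- encodeSequence(randomSequence(32, seed = 9), "C4")
  path <- withr::local_tempfile(fileext = ".png")
  writeActionImage(img, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- readActionImage(path)
  expect_identical(pixels(back), pixels(img))
  expect_identical(orderingId(back), "C4")
  expect_identical(sampleId(back), sampleId(img))
})

test_that("centralWindow picks the middle 32 frames", {
  s <- randomSequence(64, seed = 11)
  w <- centralWindow(s)
  expect_identical(nFrames(w), 32L)
  expect_identical(w@startFrame, 16L)
  expect_equal(jointCoords(w), jointCoords(s)[, , 17:48],
               ignore_attr = TRUE)
  expect_error(centralWindow(randomSequence(20, seed = 1)), "fewer")
})
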