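test_that("cross-subject splits are disjoint, complete and deterministic", {
  ds <- mockDataset(32)
  sp <- crossSubjectSplit(ds, 20, 5, 7, seed = 4)
  expect_identical(vapply(sp, length, 0L),
                   c(train = 900L, val = 225L, test = 315L))
  subj <- lapply(sp, function(d) unique(subjectId(d)))
  expect_length(intersect(subj$train, subj$val), 0L)
  expect_length(intersect(subj$train, subj$test), 0L)
  expect_length(intersect(subj$val, subj$test), 0L)
  sp2 <- crossSubjectSplit(ds, 20, 5, 7, seed = 4)
  expect_identical(subjectId(sp2$train), subjectId(sp$train))
  # subject-level assignment preserves class balance
  expect_identical(as.vector(table(classLabel(sp$train))), rep(100L, 9L))
})

test_that("subjects never leak across splits over many seeds", {
  ds <- mockDataset(8)
  for (seed in 1:20) {
    sp <- crossSubjectSplit(ds, 4, 2, 2, seed = seed)
    subj <- lapply(sp, function(d) unique(subjectId(d)))
    expect_identical(length(unlist(subj)), length(unique(unlist(subj))),
                     label = sprintf("seed %d", seed))
  }
  expect_error(crossSubjectSplit(ds, 7, 1, 1), "only 8")
  all3 <- crossSubjectSplit(ds, 8, 0, 0, seed = 1)
  expect_identical(length(all3$train), length(ds))
  expect_identical(length(all3$val), 0L)
})

test_that("accuracy arithmetic follows the confusion-matrix contract", {
  cm <- matrix(c(8, 1, 2, 9), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(accuracyFromConfusion(cm), 85)
  expect_equal(unname(perClassAccuracy(cm)), c(80, 90))
  # degenerate: everything predicted as the first class
  cm2 <- matrix(c(5, 5, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(accuracyFromConfusion(cm2), 50)
  expect_equal(unname(perClassAccuracy(cm2)), c(100, 0))
  # empty true class reported as missing, not zero
  cm3 <- matrix(c(10, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(unname(perClassAccuracy(cm3)), c(100, NA_real_))
  # accuracy from the confusion matrix equals accuracy from raw labels
  withr::with_seed(9, {
    true <- sample(letters[1:3], 60, replace = TRUE)
    pred <- sample(letters[1:3], 60, replace = TRUE)
  })
  cm4 <- confusionMatrix(true, pred, letters[1:3])
  expect_equal(accuracyFromConfusion(cm4), 100 * mean(true == pred))
  expect_identical(sum(cm4), 60L)
})

test_that("multiclass MCC reduces to the binary formula on 2 x 2 tables", {
  cm <- matrix(c(8, 1, 2, 9), 2)
  binary <- (8 * 9 - 2 * 1) / sqrt((8 + 2) * (8 + 1) * (9 + 2) * (9 + 1))
  expect_equal(mccMulticlass(cm), binary, tolerance = 1e-12)
  expect_equal(round(mccMulticlass(cm), 4), 0.7035)
  for (seed in 1:20) {
    m <- withr::with_seed(seed, matrix(rpois(4, 10), 2))
    if (sum(m) == 0) next
    tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    ref <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(mccMulticlass(m), ref, tolerance = 1e-12,
                 label = sprintf("seed %d", seed))
  }
})

test_that("multiclass MCC matches the indicator-covariance formulation", {
  expect_equal(mccMulticlass(diag(c(5, 3, 7))), 1)
  onecol <- matrix(0, 3, 3); onecol[, 1] <- c(4, 4, 4)
  expect_equal(mccMulticlass(onecol), 0)    # degenerate denominator
  for (seed in 1:15) {
    m <- withr::with_seed(100 + seed, matrix(rpois(16, 4), 4))
    expect_equal(mccMulticlass(m), mccFromIndicators(m), tolerance = 1e-9,
                 label = sprintf("seed %d", seed))
  }
})

test_that("one-way ANOVA matches the hand-computed example and df shapes", {
  res <- oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$F, 3)
  expect_identical(res$dfBetween, 2L)
  expect_identical(res$dfWithin, 6L)
  same <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  six <- withr::with_seed(3, lapply(1:6, function(i) rnorm(20)))
  res6 <- oneWayAnova(six)
  expect_identical(res6$dfBetween, 5L)     # six configurations
  expect_identical(res6$dfWithin, 114L)
  expect_warning(
    inf <- oneWayAnova(list(c(1, 1), c(2, 2))), "infinite")
  expect_identical(inf$F, Inf)
  expect_error(oneWayAnova(list(1:3)), "2 groups")
  expect_error(oneWayAnova(list(1, 1:3)), "2 values")
})

test_that("ANOVA agrees with the reference implementation to 1e-9", {
  for (seed in 1:50) {
    groups <- withr::with_seed(seed, {
      g <- sample(2:6, 1)
      lapply(seq_len(g), function(i) rnorm(sample(3:12, 1), mean = i / 3))
    })
    res <- oneWayAnova(groups)
    vals <- unlist(groups)
    fac <- factor(rep(seq_along(groups), lengths(groups)))
    ref <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
    expect_equal(res$F, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$dfBetween, unname(as.integer(ref$parameter[1])))
    expect_equal(res$dfWithin, unname(as.integer(ref$parameter[2])))
    expect_equal(res$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("the pooled t-test matches its examples and sidedness convention", {
  res <- pairwiseTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_identical(res$df, 4L)
  same <- pairwiseTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)                 # one-sided by default
  twenty <- pairwiseTTest(rnorm(20), rnorm(20))
  expect_identical(twenty$df, 38L)          # 20 + 20 - 2
  expect_error(pairwiseTTest(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(pairwiseTTest(1, c(1, 2)), "2 values")
})

test_that("the t-test agrees with the reference implementation to 1e-9", {
  for (seed in 1:50) {
    ab <- withr::with_seed(seed + 200, list(
      a = rnorm(sample(3:15, 1), mean = 0.3),
      b = rnorm(sample(3:15, 1))))
    res <- pairwiseTTest(ab$a, ab$b)
    ref <- stats::t.test(ab$a, ab$b, var.equal = TRUE,
                         alternative = "greater")
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$df, unname(as.integer(ref$parameter)))
    expect_equal(res$p, unname(ref$p.value), tolerance = 1e-9)
    res2 <- pairwiseTTest(ab$a, ab$b, oneSided = FALSE)
    ref2 <- stats::t.test(ab$a, ab$b, var.equal = TRUE)
    expect_equal(res2$p, unname(ref2$p.value), tolerance = 1e-9)
  }
})

test_that("evaluateModel reports accuracy, per-class accuracy and MCC", {
  model <- tinyTrainedModel()
  imgs <- tinyTrainImages()
  rep <- evaluateModel(model, imgs)
  expect_s4_class(rep, "RunReport")
  expect_equal(rep@accuracy, 100)
  expect_equal(unname(rep@perClass), rep(100, 9))
  expect_equal(rep@mcc, 100)
  expect_identical(sum(rep@confusion), 45L)
  expect_identical(rep@orderingId, "B1")
  expect_error(evaluateModel(model, imgs[0]), "empty")
})
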