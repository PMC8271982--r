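#' Cross-subject train/validation/test split
#'
#' Subjects (not samples) are assigned at random to the three splits, so no
#' subject ever contributes samples to more than one of them. Because each
#' subject contributes the same number of samples per class under the
#' collection protocol, subject-level assignment automatically preserves
#' class balance.
#'
#' @param ds a [LabeledDataset-class].
#' @param nTrain,nVal,nTest number of subjects per split; the total must
#'   not exceed the number of distinct subjects.
#' @param seed seed for the subject shuffle.
#' @return named list of three [LabeledDataset-class]s: \code{train},
#'   \code{val}, \code{test}.
#' @export
crossSubjectSplit <- function(ds, nTrain, nVal, nTest, seed = 1L) {
  subjects <- unique(subjectId(ds))
  need <- nTrain + nVal + nTest
  if (need > length(subjects))
    stop(sprintf("split needs %d subjects but the dataset has only %d",
                 need, length(subjects)))
  perm <- withr::with_seed(as.integer(seed), sample(subjects))
  sets <- list(train = perm[seq_len(nTrain)],
               val = if (nVal > 0) perm[nTrain + seq_len(nVal)]
                     else character(),
               test = if (nTest > 0) perm[nTrain + nVal + seq_len(nTest)]
                      else character())
  lapply(sets, function(s) ds[subjectId(ds) %in% s])
}

#' Confusion matrix from label vectors
#'
#' @param true,predicted character vectors of labels.
#' @param classes class vocabulary fixing row/column order.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusionMatrix <- function(true, predicted, classes) {
  m <- table(factor(true, levels = classes),
             factor(predicted, levels = classes))
  m <- unclass(m)
  names(dimnames(m)) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Overall and per-class accuracy of a confusion matrix
#'
#' Overall accuracy is \code{100 * trace / total}; per-class accuracy is
#' \code{100 * diagonal / row sum}, reported as \code{NA} (not zero) for
#' classes with no evaluated samples.
#'
#' @param cm square confusion matrix (rows = true class).
#' @return for [accuracyFromConfusion()] a single percentage; for
#'   [perClassAccuracy()] a named numeric vector of percentages.
#' @export
accuracyFromConfusion <- function(cm) {
  100 * sum(diag(cm)) / sum(cm)
}

#' @rdname accuracyFromConfusion
#' @export
perClassAccuracy <- function(cm) {
  rs <- rowSums(cm)
  out <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  names(out) <- rownames(cm)
  out
}

#' Multiclass Matthews correlation coefficient
#'
#' Computes the K-class generalization of the Matthews correlation
#' coefficient (Gorodkin's R_K statistic) from a confusion matrix:
#' \deqn{R_K = \frac{N \mathrm{tr}(C) - \sum_k t_k p_k}
#'   {\sqrt{N^2 - \sum_k t_k^2} \sqrt{N^2 - \sum_k p_k^2}}}
#' with \eqn{t_k} the true and \eqn{p_k} the predicted class totals. For
#' K = 2 this reduces exactly to the binary Matthews correlation. A
#' degenerate denominator (all mass in one true or one predicted class)
#' yields 0.
#'
#' @param cm square confusion matrix with a positive total.
#' @return a value in \code{[-1, 1]}.
#' @examples
#' mccMulticlass(matrix(c(8, 1, 2, 9), 2))   # 0.7035...
#' @export
mccMulticlass <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix total must be > 0")
  tk <- rowSums(cm)   # true totals
  pk <- colSums(cm)   # predicted totals
  num <- n * sum(diag(cm)) - sum(tk * pk)
  den <- sqrt(n^2 - sum(tk^2)) * sqrt(n^2 - sum(pk^2))
  if (den == 0) return(0)
  num / den
}

#' Evaluate a trained model on a labeled image dataset
#'
#' @param model a [TrainedModel-class].
#' @param ds a non-empty [LabeledDataset-class] of [ActionImage-class]
#'   samples whose ordering matches the model's.
#' @return a [RunReport-class] with accuracy and MCC in percent, per-class
#'   accuracies and the confusion matrix.
#' @export
evaluateModel <- function(model, ds) {
  if (length(ds) == 0L) stop("evaluation dataset is empty")
  probs <- predictBatch(model, ds)
  pred <- model@classes[max.col(probs, ties.method = "first")]
  cm <- confusionMatrix(classLabel(ds), pred, model@classes)
  new("RunReport", seed = model@seed,
      accuracy = accuracyFromConfusion(cm),
      perClass = perClassAccuracy(cm),
      mcc = 100 * mccMulticlass(cm),
      confusion = cm,
      orderingId = model@orderingId)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA across g groups:
#' F = (SSB / (g - 1)) / (SSW / (N - g)), reported with
#' df_between = g - 1 and df_within = N - g (so six groups of 20 runs give
#' F(5, 114)).
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list with \code{F}, \code{dfBetween}, \code{dfWithin}, \code{p}.
#'   Zero within-group variance with between-group differences yields an
#'   infinite F with a warning.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$F   # 3
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs at least 2 values")
  ni <- vapply(groups, length, 0L)
  n <- sum(ni)
  g <- length(groups)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, 0)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  dfb <- g - 1L
  dfw <- n - g
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, dfBetween = dfb, dfWithin = dfw, p = 1))
    warning("zero within-group variance; F is infinite")
    return(list(F = Inf, dfBetween = dfb, dfWithin = dfw, p = 0))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, dfBetween = dfb, dfWithin = dfw,
       p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

#' Independent two-sample Student's t-test (pooled variance)
#'
#' Pooled-variance t statistic with df = n1 + n2 - 2. The default p value
#' is one-sided, for the alternative that the first sample's mean exceeds
#' the second's (the experiment harness passes the control configuration
#' first): p = P(T >= t). Identical samples therefore give t = 0 and
#' p = 0.5.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @param oneSided if \code{TRUE} (default) the one-sided p above; otherwise
#'   the two-sided p.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @examples
#' pairwiseTTest(c(1, 2, 3), c(2, 3, 4))   # t = -1.2247, df = 4
#' @export
pairwiseTTest <- function(a, b, oneSided = TRUE) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 values")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (sp2 == 0) stop("zero pooled variance; t statistic undefined")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- if (oneSided) stats::pt(t, df, lower.tail = FALSE)
       else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
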