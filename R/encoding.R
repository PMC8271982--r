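#' Min--max normalize a coordinate to the 0--255 intensity range
#'
#' Applies the per-sequence normalization
#' \deqn{k' = 255 (k - \min_c) / (\max_c - \min_c)}
#' where the minimum and maximum are taken over all joints and frames of the
#' sequence being encoded (per axis). The map is invariant to translating
#' the axis by a constant and to scaling it by a positive factor.
#'
#' @param k numeric vector of coordinate values.
#' @param cmin,cmax the axis minimum and maximum over the sequence
#'   (\code{cmax >= cmin}).
#' @return numeric vector of values in \code{[0, 255]}. When
#'   \code{cmax == cmin} the range is degenerate and 0 is returned for every
#'   value, with a warning.
#' @examples
#' normalizeCoordinate(4, 0, 10)   # 102
#' @export
normalizeCoordinate <- function(k, cmin, cmax) {
  if (!all(is.finite(k)) || !is.finite(cmin) || !is.finite(cmax))
    stop("non-finite input to normalizeCoordinate")
  if (cmax < cmin) stop("cmax must be >= cmin")
  if (cmax == cmin) {
    warning("degenerate coordinate range (cmax == cmin); returning 0")
    return(rep(0, length(k)))
  }
  255 * (k - cmin) / (cmax - cmin)
}

# Encoding kernel on a raw [J, 3, N] coordinate array. Per-axis min/max are
# pooled over all joints and frames; values are rounded half-up to integers.
# Returns an integer [J, N, 3] pixel array with rows permuted by `ordSeq`.
.encodeCoords <- function(coords, ordSeq) {
  d <- dim(coords)
  pix <- array(0L, dim = c(d[1], d[3], 3L))
  for (a in 1:3) {
    v <- coords[, a, , drop = FALSE]
    cmin <- min(v); cmax <- max(v)
    if (cmax == cmin) {
      warning(sprintf(
        "axis %s has a degenerate range; channel set to 0",
        c("x", "y", "z")[a]))
      next
    }
    # round half-up (floor(x + 0.5)), not banker's rounding
    pix[, , a] <- matrix(
      as.integer(floor(255 * (v[, 1, ] - cmin) / (cmax - cmin) + 0.5)),
      d[1], d[3])
  }
  pix[ordSeq, , , drop = FALSE]
}

#' Encode a 32-frame skeleton sequence as a color action image
#'
#' Maps a skeleton sequence onto its 15 x 32 x 3 image representation:
#' rows are joints in the order given by \code{ordering} (first listed joint
#' at the top), columns are the 32 frames (earliest at the left), and the
#' three channels carry the normalized x, y and z coordinates
#' (R = x, G = y, B = z). Normalization statistics are computed per axis
#' over all 15 joints and 32 frames of this sequence (see
#' [normalizeCoordinate()]), so the image is invariant to translation and
#' positive scaling of the raw coordinates and identical row content is
#' produced under every ordering -- orderings only permute rows.
#'
#' @param seq a [SkeletonSequence-class] with exactly 32 frames.
#' @param ordering a [JointOrdering-class] or a registered ordering id
#'   (default \code{"B1"}).
#' @return an [ActionImage-class].
#' @seealso [slidingWindows()] to cut longer streams into 32-frame windows,
#'   [centralWindow()] for the central window of a longer recording.
#' @export
encodeSequence <- function(seq, ordering = "B1") {
  seq <- validateSequence(seq)
  ordering <- getOrdering(ordering)
  n <- nFrames(seq)
  if (n != 32L)
    stop(sprintf(paste0(
      "sequence has %d frames but encoding requires exactly 32; use ",
      "slidingWindows() or centralWindow() to extract 32-frame windows"), n))
  pix <- .encodeCoords(seq@coords, orderingSequence(ordering))
  new("ActionImage", pixels = pix, orderingId = orderingId(ordering),
      sampleId = seq@sampleId, windowStart = seq@startFrame,
      label = seq@label)
}

#' Cut a skeleton stream into fixed-length sliding windows
#'
#' Windows start at frames 0, stride, 2*stride, ... (0-based) and each
#' contains exactly \code{length} frames; a stream shorter than one window
#' yields an empty list. The number of windows is
#' \code{floor((N - length) / stride) + 1} for \code{N >= length}.
#'
#' @param stream a [SkeletonSequence-class] of any length.
#' @param length window length in frames (default 32, one to two seconds of
#'   movement at typical sensor frame rates).
#' @param stride step between window starts in frames (default 1).
#' @return list of [SkeletonSequence-class] windows with
#'   \code{startFrame} set.
#' @examples
#' s <- SkeletonSequence(array(rnorm(15 * 3 * 64), c(15, 3, 64)))
#' length(slidingWindows(s, 32, 32))   # 2
#' @export
slidingWindows <- function(stream, length = 32L, stride = 1L) {
  stopifnot(is(stream, "SkeletonSequence"), length >= 1L, stride >= 1L)
  n <- nFrames(stream)
  if (n < length) {
    message(sprintf("stream of %d frames is shorter than one %d-frame window",
                    n, length))
    return(list())
  }
  starts <- seq.int(0L, n - length, by = stride)
  lapply(starts, function(s0) {
    new("SkeletonSequence",
        coords = stream@coords[, , (s0 + 1):(s0 + length), drop = FALSE],
        subject = stream@subject, label = stream@label,
        viewpoint = stream@viewpoint, sampleId = stream@sampleId,
        startFrame = as.integer(stream@startFrame + s0))
  })
}

#' Extract the central window of a longer recording
#'
#' @param seq a [SkeletonSequence-class] with at least \code{length} frames.
#' @param length window length in frames (default 32).
#' @return a [SkeletonSequence-class] of \code{length} frames centered in
#'   the recording.
#' @export
centralWindow <- function(seq, length = 32L) {
  n <- nFrames(seq)
  if (n < length)
    stop(sprintf("sequence has %d frames, fewer than the %d requested",
                 n, length))
  s0 <- (n - length) %/% 2L
  new("SkeletonSequence",
      coords = seq@coords[, , (s0 + 1):(s0 + length), drop = FALSE],
      subject = seq@subject, label = seq@label, viewpoint = seq@viewpoint,
      sampleId = seq@sampleId,
      startFrame = as.integer(seq@startFrame + s0))
}

#' Encode every sample of a dataset
#'
#' Converts a dataset of skeleton sequences into a dataset of action images
#' under one joint ordering. Recordings longer than 32 frames contribute
#' their central 32-frame window.
#'
#' @param ds a [LabeledDataset-class] of [SkeletonSequence-class] samples.
#' @param ordering a [JointOrdering-class] or registered id (default
#'   \code{"B1"}).
#' @return a [LabeledDataset-class] of [ActionImage-class] samples.
#' @export
encodeDataset <- function(ds, ordering = "B1") {
  ordering <- getOrdering(ordering)
  imgs <- lapply(ds@samples, function(s)
    encodeSequence(centralWindow(s), ordering))
  new("LabeledDataset", samples = imgs, label = ds@label,
      subject = ds@subject, viewpoint = ds@viewpoint, classes = ds@classes)
}
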