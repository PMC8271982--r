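#' The canonical 15-joint skeleton
#'
#' Full-body trackers report up to 19 joints; the recognition pipeline keeps
#' 15 of them: head, neck and spine/torso, shoulder/elbow/wrist of each arm,
#' and hip/knee/ankle of each leg (hand joints are excluded as unreliable).
#' Joints are numbered 1--15 in a fixed canonical order:
#' 1 head, 2 neck, 3 torso, 4--6 left shoulder/elbow/wrist,
#' 7--9 right shoulder/elbow/wrist, 10--12 left hip/knee/ankle,
#' 13--15 right hip/knee/ankle.
#'
#' @return character vector of length 15, the canonical joint names in index
#'   order.
#' @examples
#' jointNames()[4:6]   # the left arm
#' @export
jointNames <- function() {
  c("head", "neck", "torso",
    "left shoulder", "left elbow", "left wrist",
    "right shoulder", "right elbow", "right wrist",
    "left hip", "left knee", "left ankle",
    "right hip", "right knee", "right ankle")
}

#' Limb groups of the canonical skeleton
#'
#' The skeleton is partitioned into four limbs and one trunk: P1 left arm
#' (joints 4, 5, 6), P2 right arm (7, 8, 9), P3 torso (1, 2, 3), P4 left leg
#' (10, 11, 12) and P5 right leg (13, 14, 15). Group-level joint orderings
#' (\code{B1}--\code{B6}) concatenate these triples whole, preserving the
#' within-group order.
#'
#' @return named list of integer triples \code{P1}..\code{P5}.
#' @examples
#' jointGroups()$P1
#' @export
jointGroups <- function() {
  list(P1 = 4:6, P2 = 7:9, P3 = 1:3, P4 = 10:12, P5 = 13:15)
}

# B-configurations as group orders; C-configurations as literal joint orders.
.bGroupOrders <- list(
  B1 = c("P1", "P2", "P3", "P4", "P5"),
  B2 = c("P1", "P3", "P2", "P4", "P5"),
  B3 = c("P1", "P4", "P3", "P2", "P5"),
  B4 = c("P5", "P2", "P4", "P3", "P1"),
  B5 = c("P3", "P1", "P2", "P4", "P5"),
  B6 = c("P5", "P4", "P3", "P2", "P1")
)

.cSequences <- list(
  C2 = c(5L, 13L, 11L, 8L, 3L, 6L, 2L, 9L, 15L, 10L, 7L, 12L, 1L, 4L, 14L),
  C3 = c(2L, 9L, 14L, 12L, 5L, 11L, 8L, 6L, 3L, 7L, 13L, 4L, 15L, 1L, 10L),
  C4 = c(15L, 7L, 6L, 13L, 4L, 12L, 3L, 1L, 2L, 11L, 8L, 14L, 5L, 10L, 9L),
  C5 = c(11L, 10L, 1L, 12L, 15L, 2L, 5L, 6L, 14L, 3L, 9L, 4L, 13L, 8L, 7L)
)

.orderingRegistry <- local({
  g <- list(P1 = 4:6, P2 = 7:9, P3 = 1:3, P4 = 10:12, P5 = 13:15)
  reg <- lapply(.bGroupOrders,
                function(ord) as.integer(unlist(g[ord], use.names = FALSE)))
  c(reg, .cSequences)
})

#' Ids of all registered joint orderings
#'
#' @return character vector: \code{B1}--\code{B6} and \code{C2}--\code{C5}.
#' @export
registeredOrderings <- function() names(.orderingRegistry)

#' Look up a registered joint ordering
#'
#' \code{B1} is the control configuration: the concatenation of groups
#' P1, P2, P3, P4, P5, i.e. joints
#' \code{4 5 6 7 8 9 1 2 3 10 11 12 13 14 15}. \code{B2}--\code{B6} reorder
#' the groups; \code{C2}--\code{C5} shuffle individual joints.
#'
#' @param id a registered configuration id (see [registeredOrderings()]), or
#'   a [JointOrdering-class] which is returned unchanged.
#' @return a [JointOrdering-class].
#' @examples
#' orderingSequence(getOrdering("B1"))
#' @export
getOrdering <- function(id) {
  if (is(id, "JointOrdering")) return(id)
  if (!is.character(id) || length(id) != 1L)
    stop("ordering id must be a single string")
  if (!id %in% names(.orderingRegistry))
    stop(sprintf("unknown ordering '%s'; registered orderings: %s", id,
                 paste(names(.orderingRegistry), collapse = ", ")))
  new("JointOrdering", id = id, sequence = .orderingRegistry[[id]])
}

#' Define a custom joint ordering
#'
#' @param id label for the ordering.
#' @param sequence a permutation of \code{1:15}.
#' @return a [JointOrdering-class].
#' @export
jointOrdering <- function(id, sequence) {
  new("JointOrdering", id = id, sequence = as.integer(sequence))
}

#' Select the 15 canonical joints from a raw tracker frame
#'
#' Tracker SDKs report more joints than the pipeline uses (typically 19,
#' including the hands). This function keeps exactly the 15 canonical joints
#' by name and silently discards anything else; it is defined by the
#' keep-list, not by a drop-list, so extra joints of any name are tolerated.
#'
#' @param raw a named list of length-3 numeric coordinate vectors, or a
#'   numeric matrix with 3 columns and joint names as row names. Names must
#'   include all entries of [jointNames()]; matching is case-insensitive and
#'   ignores underscores.
#' @return a 15 x 3 numeric matrix (rows in canonical order, columns x/y/z).
#' @examples
#' raw <- matrix(rnorm(19 * 3), 19, 3,
#'               dimnames = list(c(jointNames(), "left hand", "right hand",
#'                                 "left foot", "right foot"), NULL))
#' dim(selectJoints(raw))
#' @export
selectJoints <- function(raw) {
  if (is.list(raw) && !is.data.frame(raw)) {
    nm <- names(raw)
    coords <- do.call(rbind, lapply(raw, function(v) as.numeric(v)[1:3]))
    rownames(coords) <- nm
    raw <- coords
  }
  if (!is.matrix(raw) || ncol(raw) < 3L || is.null(rownames(raw)))
    stop("raw frame must be a named list or a matrix with joint row names")
  canon <- function(x) gsub("[_ ]+", " ", tolower(trimws(x)))
  have <- canon(rownames(raw))
  want <- canon(jointNames())
  idx <- match(want, have)
  if (anyNA(idx)) {
    miss <- jointNames()[is.na(idx)]
    stop(sprintf("missing joint%s: %s", if (length(miss) > 1) "s" else "",
                 paste(miss, collapse = ", ")))
  }
  out <- unname(raw[idx, 1:3, drop = FALSE])
  if (!all(is.finite(out))) {
    bad <- jointNames()[which(rowSums(!is.finite(out)) > 0)]
    stop(sprintf("non-finite coordinate for joint%s: %s",
                 if (length(bad) > 1) "s" else "",
                 paste(bad, collapse = ", ")))
  }
  dimnames(out) <- list(jointNames(), c("x", "y", "z"))
  out
}

#' Construct a skeleton sequence
#'
#' @param coords numeric array \code{[15, 3, N]} (joints x axes x frames),
#'   or a list of 15 x 3 per-frame matrices (e.g. from [selectJoints()]).
#' @param subject,label,viewpoint,sampleId optional metadata.
#' @param startFrame 0-based start frame within the source stream.
#' @return a [SkeletonSequence-class].
#' @export
SkeletonSequence <- function(coords, subject = NA_character_,
                             label = NA_character_,
                             viewpoint = NA_character_,
                             sampleId = NA_character_, startFrame = 0L) {
  if (is.list(coords)) {
    if (length(coords) == 0L) stop("N must be >= 1 (sequence has no frames)")
    coords <- array(unlist(lapply(coords, function(m) as.numeric(m))),
                    dim = c(15L, 3L, length(coords)))
  }
  dimnames(coords) <- list(jointNames(), c("x", "y", "z"), NULL)
  new("SkeletonSequence", coords = coords,
      subject = as.character(subject), label = as.character(label),
      viewpoint = as.character(viewpoint), sampleId = as.character(sampleId),
      startFrame = as.integer(startFrame))
}

#' Validate a skeleton sequence frame by frame
#'
#' Checks that the sequence has at least one frame and that every frame
#' holds finite coordinates for all 15 joints; the error message names the
#' first offending frame (1-based).
#'
#' @param seq a [SkeletonSequence-class].
#' @return \code{seq}, unchanged, if valid.
#' @export
validateSequence <- function(seq) {
  if (!is(seq, "SkeletonSequence"))
    stop("seq must be a SkeletonSequence")
  n <- nFrames(seq)
  if (n < 1L) stop("N must be >= 1 (sequence has no frames)")
  fin <- apply(is.finite(seq@coords), 3, all)
  if (!all(fin)) {
    f <- which(!fin)[1]
    bad <- which(!apply(is.finite(seq@coords[, , f, drop = FALSE])[, , 1],
                        1, all))[1]
    stop(sprintf("frame %d has a non-finite coordinate (joint '%s')",
                 f, jointNames()[bad]))
  }
  seq
}
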