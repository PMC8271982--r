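#' @useDynLib skelact, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' JointOrdering: a registered permutation of the 15 skeleton joints
#'
#' A \code{JointOrdering} fixes the order in which the 15 canonical joints
#' become rows of an encoded action image. The built-in registry holds the
#' group-level configurations \code{B1}--\code{B6} (whole limb groups
#' reordered) and the fully shuffled configurations \code{C2}--\code{C5};
#' \code{B1} is the control ordering: left arm, right arm, torso, left leg,
#' right leg.
#'
#' @slot id single character label (e.g. \code{"B1"}).
#' @slot sequence integer vector of length 15; a permutation of \code{1:15}
#'   giving the joint index shown in each image row, top row first.
#'
#' @seealso [getOrdering()], [registeredOrderings()], [encodeSequence()]
#' @export
setClass("JointOrdering",
  representation(id = "character", sequence = "integer"),
  validity = function(object) {
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
      return("id must be a single non-empty string")
    if (length(object@sequence) != 15L ||
        !identical(sort(object@sequence), 1:15))
      return("sequence must be a permutation of 1:15")
    TRUE
  }
)

#' SkeletonSequence: an ordered run of 15-joint skeleton frames
#'
#' Coordinates are stored as a numeric array of dimension
#' \code{c(15, 3, N)}: 15 canonical joints (see [jointNames()]), three axes
#' (x, y, z, nominally meters in the sensor camera frame), and N frames.
#' Joints are always stored in canonical index order 1--15; a
#' [JointOrdering-class] is applied only at encoding time.
#'
#' @slot coords numeric array \code{[15, 3, N]}.
#' @slot subject subject identifier (may be \code{NA}).
#' @slot label action class label (may be \code{NA}).
#' @slot viewpoint one of \code{"front"}, \code{"left"}, \code{"right"}, or
#'   \code{NA}.
#' @slot sampleId sample identifier (may be \code{NA}).
#' @slot startFrame 0-based start frame of this sequence within its source
#'   stream (0 for raw recordings; set by [slidingWindows()]).
#'
#' @seealso [SkeletonSequence()], [validateSequence()], [encodeSequence()]
#' @export
setClass("SkeletonSequence",
  representation(coords = "array", subject = "character",
                 label = "character", viewpoint = "character",
                 sampleId = "character", startFrame = "integer"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[1] != 15L || d[2] != 3L)
      return("coords must be a [15, 3, N] array")
    if (d[3] < 1L) return("N must be >= 1 (sequence has no frames)")
    for (s in c("subject", "label", "viewpoint", "sampleId"))
      if (length(slot(object, s)) != 1L)
        return(sprintf("%s must be a single value", s))
    if (!object@viewpoint %in% c("front", "left", "right", NA_character_))
      return("viewpoint must be 'front', 'left', 'right' or NA")
    TRUE
  }
)

#' ActionImage: the 15 x 32 x 3 color-image encoding of a sequence
#'
#' Row r is the r-th joint of the applied ordering (row 1 at the top of the
#' image), column f is frame f of the 32-frame window (column 1 at the left),
#' and the channels carry the per-sequence min--max normalized coordinates
#' with R = x, G = y, B = z. All values are integers in 0--255.
#'
#' @slot pixels integer array \code{[15, 32, 3]} with values in 0--255.
#' @slot orderingId id of the [JointOrdering-class] used for the rows.
#' @slot sampleId source sample identifier (may be \code{NA}).
#' @slot windowStart 0-based start frame of the encoded window.
#' @slot label action class label carried over from the source (may be
#'   \code{NA}).
#'
#' @seealso [encodeSequence()], [writeActionImage()]
#' @export
setClass("ActionImage",
  representation(pixels = "array", orderingId = "character",
                 sampleId = "character", windowStart = "integer",
                 label = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || !all(d == c(15L, 32L, 3L)))
      return("pixels must be a [15, 32, 3] array")
    if (!is.integer(object@pixels) || anyNA(object@pixels))
      return("pixels must be integers with no missing values")
    if (min(object@pixels) < 0L || max(object@pixels) > 255L)
      return("pixel values must lie in [0, 255]")
    if (length(object@orderingId) != 1L)
      return("orderingId must be a single string")
    TRUE
  }
)

#' LabeledDataset: labeled samples with subject and viewpoint metadata
#'
#' Holds either [SkeletonSequence-class] samples (raw) or
#' [ActionImage-class] samples (encoded), together with their class labels,
#' subject ids and viewpoints. Supports subsetting with \code{[} and
#' cross-subject splitting with [crossSubjectSplit()].
#'
#' @slot samples list of samples, all of the same class.
#' @slot label character vector of class labels, one per sample.
#' @slot subject character vector of subject ids, one per sample.
#' @slot viewpoint character vector of viewpoints, one per sample.
#' @slot classes the class vocabulary (superset of used labels).
#'
#' @export
setClass("LabeledDataset",
  representation(samples = "list", label = "character",
                 subject = "character", viewpoint = "character",
                 classes = "character"),
  validity = function(object) {
    n <- length(object@samples)
    if (length(object@label) != n || length(object@subject) != n ||
        length(object@viewpoint) != n)
      return("label, subject and viewpoint must have one entry per sample")
    if (n > 0L) {
      cls <- unique(vapply(object@samples, function(s) class(s)[1], ""))
      if (length(cls) > 1L)
        return("samples must all be of the same class")
      if (!cls %in% c("SkeletonSequence", "ActionImage"))
        return("samples must be SkeletonSequence or ActionImage objects")
      if (!all(object@label %in% object@classes))
        return("every label must be in the class vocabulary")
      if (any(!nzchar(object@subject) | is.na(object@subject)))
        return("subject ids must be non-empty")
    }
    TRUE
  }
)

#' TrainedModel: the convolutional classifier with learned parameters
#'
#' Wraps the parameter set of the six-convolution network (64, 64, 128, 128,
#' 256, 256 filters of size 3 x 3, batch normalization + ReLU, 2 x 2
#' max-pooling after conv 2 and conv 4, global average pooling, one fully
#' connected softmax head) together with its label vocabulary, the joint
#' ordering its inputs must use, and training provenance.
#'
#' @slot params named list of weight matrices and batch-norm statistics.
#' @slot classes label vocabulary; its length equals the softmax width.
#' @slot orderingId ordering id the model was built/trained for
#'   (\code{NA} until trained).
#' @slot history data.frame with per-epoch training loss and accuracy
#'   (zero rows for an untrained model).
#' @slot seed integer seed used for initialization/training.
#' @slot config training configuration list (see [trainingConfig()]).
#'
#' @seealso [buildModel()], [trainModel()], [predictAction()]
#' @export
setClass("TrainedModel",
  representation(params = "list", classes = "character",
                 orderingId = "character", history = "data.frame",
                 seed = "integer", config = "list"),
  validity = function(object) {
    if (length(object@classes) < 2L)
      return("model must have at least 2 classes")
    if (!is.null(object@params$Wfc) &&
        ncol(object@params$Wfc) != length(object@classes))
      return("label vocabulary size must equal the softmax output width")
    TRUE
  }
)

#' RunReport: evaluation result of one trained model on one dataset
#'
#' @slot seed training seed of the evaluated run.
#' @slot accuracy overall accuracy in percent.
#' @slot perClass named numeric vector of per-class accuracies in percent;
#'   \code{NA} for classes absent from the evaluation set.
#' @slot mcc multiclass Matthews correlation coefficient in percent.
#' @slot confusion K x K confusion matrix (rows = true, columns = predicted).
#' @slot orderingId ordering id of the evaluated configuration.
#'
#' @seealso [evaluateModel()]
#' @export
setClass("RunReport",
  representation(seed = "integer", accuracy = "numeric",
                 perClass = "numeric", mcc = "numeric",
                 confusion = "matrix", orderingId = "character"),
  validity = function(object) {
    if (object@accuracy < 0 || object@accuracy > 100)
      return("accuracy must be reported in percent (0..100)")
    if (!is.na(object@mcc) && (object@mcc < -100 || object@mcc > 100))
      return("MCC must be reported in percent (-100..100)")
    if (nrow(object@confusion) != ncol(object@confusion))
      return("confusion matrix must be square")
    TRUE
  }
)

#' ExperimentReport: repeated-runs comparison of joint orderings
#'
#' Aggregates the per-run reports of each joint-ordering configuration,
#' their mean and standard deviation, a one-way ANOVA across configurations,
#' and pairwise pooled t-tests of the control ordering (first configuration,
#' normally \code{B1}) against each other configuration.
#'
#' @slot kind experiment kind, \code{"E1"} (group-level orderings) or
#'   \code{"E2"} (fully shuffled orderings).
#' @slot configIds configuration ids, control first.
#' @slot runs named list; one list of [RunReport-class] per configuration.
#' @slot summary data.frame with columns \code{config}, \code{mean},
#'   \code{sd} (accuracy in percent).
#' @slot anova list with \code{F}, \code{dfBetween}, \code{dfWithin},
#'   \code{p}.
#' @slot ttests data.frame with columns \code{config}, \code{t}, \code{df},
#'   \code{p} for each non-control configuration (uncorrected p values; the
#'   number of comparisons equals \code{nrow(ttests)}).
#'
#' @seealso [runExperiment()]
#' @export
setClass("ExperimentReport",
  representation(kind = "character", configIds = "character",
                 runs = "list", summary = "data.frame", anova = "list",
                 ttests = "data.frame"),
  validity = function(object) {
    if (!object@kind %in% c("E1", "E2", "custom"))
      return("kind must be 'E1', 'E2' or 'custom'")
    if (length(object@runs) != length(object@configIds))
      return("one run list per configuration required")
    TRUE
  }
)
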