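#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: number of frames,
#' coordinate array, metadata fields, ordering sequence and pixel array.
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("jointCoords", function(x) standardGeneric("jointCoords"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname accessors
#' @export
setGeneric("viewpoint", function(x) standardGeneric("viewpoint"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("orderingId", function(x) standardGeneric("orderingId"))

#' @rdname accessors
#' @export
setGeneric("orderingSequence", function(x) standardGeneric("orderingSequence"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("classVocabulary", function(x) standardGeneric("classVocabulary"))

# ---- SkeletonSequence ----

#' @rdname accessors
#' @export
setMethod("nFrames", "SkeletonSequence", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setMethod("jointCoords", "SkeletonSequence", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("subjectId", "SkeletonSequence", function(x) x@subject)

#' @rdname accessors
#' @export
setMethod("classLabel", "SkeletonSequence", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("viewpoint", "SkeletonSequence", function(x) x@viewpoint)

#' @rdname accessors
#' @export
setMethod("sampleId", "SkeletonSequence", function(x) x@sampleId)

setMethod("show", "SkeletonSequence", function(object) {
  cat(sprintf("SkeletonSequence: %d frames x 15 joints\n",
              nFrames(object)))
  cat(sprintf("  sample: %s  subject: %s  label: %s  viewpoint: %s\n",
              object@sampleId, object@subject, object@label,
              object@viewpoint))
})

# ---- JointOrdering ----

#' @rdname accessors
#' @export
setMethod("orderingId", "JointOrdering", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("orderingSequence", "JointOrdering", function(x) x@sequence)

setMethod("show", "JointOrdering", function(object) {
  cat(sprintf("JointOrdering '%s': %s\n", object@id,
              paste(object@sequence, collapse = " ")))
})

# ---- ActionImage ----

#' @rdname accessors
#' @export
setMethod("pixels", "ActionImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("orderingId", "ActionImage", function(x) x@orderingId)

#' @rdname accessors
#' @export
setMethod("sampleId", "ActionImage", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("classLabel", "ActionImage", function(x) x@label)

setMethod("show", "ActionImage", function(object) {
  cat(sprintf(
    "ActionImage: 15 x 32 x 3, ordering %s, sample %s, window start %d\n",
    object@orderingId, object@sampleId, object@windowStart))
})

# ---- LabeledDataset ----

#' @rdname accessors
#' @export
setMethod("nSamples", "LabeledDataset", function(x) length(x@samples))

#' @rdname accessors
#' @export
setMethod("classLabel", "LabeledDataset", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("subjectId", "LabeledDataset", function(x) x@subject)

#' @rdname accessors
#' @export
setMethod("viewpoint", "LabeledDataset", function(x) x@viewpoint)

#' @rdname accessors
#' @export
setMethod("classVocabulary", "LabeledDataset", function(x) x@classes)

#' @export
setMethod("length", "LabeledDataset", function(x) length(x@samples))

#' Subset a labeled dataset
#'
#' @param x a [LabeledDataset-class].
#' @param i numeric or logical index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "LabeledDataset", function(x, i, j, ..., drop = FALSE) {
  new("LabeledDataset", samples = x@samples[i], label = x@label[i],
      subject = x@subject[i], viewpoint = x@viewpoint[i],
      classes = x@classes)
})

#' Extract one sample from a labeled dataset
#'
#' @param x a [LabeledDataset-class].
#' @param i single index.
#' @param exact ignored.
#' @export
setMethod("[[", "LabeledDataset", function(x, i, exact = TRUE) x@samples[[i]])

setMethod("show", "LabeledDataset", function(object) {
  kind <- if (length(object@samples) > 0L) class(object@samples[[1]])[1]
          else "empty"
  cat(sprintf("LabeledDataset: %d samples (%s)\n", length(object@samples),
              kind))
  cat(sprintf("  classes (%d): %s\n", length(object@classes),
              paste(object@classes, collapse = ", ")))
  cat(sprintf("  subjects: %d  viewpoints: %s\n",
              length(unique(object@subject)),
              paste(unique(object@viewpoint), collapse = "/")))
})

# ---- TrainedModel ----

#' @rdname accessors
#' @export
setMethod("orderingId", "TrainedModel", function(x) x@orderingId)

#' @rdname accessors
#' @export
setMethod("classVocabulary", "TrainedModel", function(x) x@classes)

setMethod("show", "TrainedModel", function(object) {
  trained <- nrow(object@history) > 0L
  cat(sprintf("TrainedModel: %d classes, ordering %s (%s)\n",
              length(object@classes), object@orderingId,
              if (trained) sprintf("trained %d epochs", nrow(object@history))
              else "untrained"))
})

# ---- RunReport ----

setMethod("show", "RunReport", function(object) {
  cat(sprintf(
    "RunReport (seed %d, ordering %s): accuracy %.1f%%, MCC %.1f%%\n",
    object@seed, object@orderingId, object@accuracy, object@mcc))
})

# ---- ExperimentReport ----

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf("ExperimentReport %s: %d configurations x %d runs\n",
              object@kind, length(object@configIds),
              length(object@runs[[1]])))
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %5.1f%% +/- %.1f%%\n", s$config[i], s$mean[i],
                s$sd[i]))
  a <- object@anova
  cat(sprintf("  ANOVA: F(%d, %d) = %.2f, p = %.3g\n", a$dfBetween,
              a$dfWithin, a$F, a$p))
})
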