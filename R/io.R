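#' Read and write skeleton sequences as CSV
#'
#' The skeleton CSV format has one row per frame per joint with columns
#' \code{sample_id, frame, joint_index, joint_name, x, y, z} (frames
#' 1-based; joint indices canonical 1--15). One file may hold many samples;
#' see \code{system.file("extdata", "skeleton_csv_schema.json",
#' package = "skelact")} for the schema.
#'
#' @param ds a [LabeledDataset-class] or a single [SkeletonSequence-class].
#' @param path file path.
#' @return \code{readSkeletonCSV} returns a [LabeledDataset-class] (sample
#'   metadata other than \code{sample_id} is recovered from \code{manifest}
#'   if supplied); \code{writeSkeletonCSV} returns \code{path} invisibly.
#' @param manifest optional data.frame with columns \code{sample_id},
#'   \code{subject}, \code{class}, \code{viewpoint} used to re-attach
#'   metadata on read.
#' @export
writeSkeletonCSV <- function(ds, path) {
  if (is(ds, "SkeletonSequence"))
    ds <- new("LabeledDataset", samples = list(ds), label = ds@label,
              subject = ifelse(is.na(ds@subject), "S00", ds@subject),
              viewpoint = ds@viewpoint,
              classes = unique(stats::na.omit(ds@label)))
  rows <- lapply(seq_len(length(ds)), function(i) {
    s <- ds[[i]]
    n <- nFrames(s)
    data.frame(
      sample_id = if (is.na(s@sampleId)) sprintf("sample%04d", i)
                  else s@sampleId,
      frame = rep(seq_len(n), each = 15L),
      joint_index = rep(1:15, n),
      joint_name = rep(jointNames(), n),
      x = as.vector(s@coords[, 1, ]),
      y = as.vector(s@coords[, 2, ]),
      z = as.vector(s@coords[, 3, ]),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSkeletonCSV
#' @export
readSkeletonCSV <- function(path, manifest = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "frame", "joint_index", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop(sprintf("skeleton CSV must have columns %s",
                 paste(need, collapse = ", ")))
  ids <- unique(df$sample_id)
  samples <- vector("list", length(ids))
  meta <- data.frame(sample_id = ids, subject = NA_character_,
                     class = NA_character_, viewpoint = NA_character_,
                     stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    m <- match(ids, manifest$sample_id)
    meta$subject <- manifest$subject[m]
    meta$class <- manifest$class[m]
    meta$viewpoint <- manifest$viewpoint[m]
  }
  for (i in seq_along(ids)) {
    d <- df[df$sample_id == ids[i], ]
    d <- d[order(d$frame, d$joint_index), ]
    n <- length(unique(d$frame))
    if (nrow(d) != 15L * n)
      stop(sprintf("sample '%s' does not have 15 joints in every frame",
                   ids[i]))
    coords <- array(0, dim = c(15L, 3L, n))
    coords[, 1, ] <- matrix(d$x, 15L, n)
    coords[, 2, ] <- matrix(d$y, 15L, n)
    coords[, 3, ] <- matrix(d$z, 15L, n)
    samples[[i]] <- SkeletonSequence(
      coords, subject = meta$subject[i], label = meta$class[i],
      viewpoint = meta$viewpoint[i], sampleId = ids[i])
  }
  subj <- ifelse(is.na(meta$subject), "unknown", meta$subject)
  new("LabeledDataset", samples = samples,
      label = meta$class, subject = subj, viewpoint = meta$viewpoint,
      classes = unique(stats::na.omit(meta$class)))
}

#' Read and write a skeleton sequence as JSON lines
#'
#' One frame object per line:
#' \code{{"sample_id": ..., "frame": f, "joints": {"head": [x,y,z], ...}}}.
#'
#' @param seq a [SkeletonSequence-class].
#' @param path file path.
#' @return \code{readSkeletonJSONL} returns a [SkeletonSequence-class];
#'   \code{writeSkeletonJSONL} returns \code{path} invisibly.
#' @export
writeSkeletonJSONL <- function(seq, path) {
  stopifnot(is(seq, "SkeletonSequence"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(seq))) {
    joints <- lapply(seq_len(15L), function(j) unname(seq@coords[j, , f]))
    names(joints) <- jointNames()
    line <- jsonlite::toJSON(
      list(sample_id = seq@sampleId, frame = f, joints = joints),
      auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(line, con)
  }
  invisible(path)
}

#' @rdname writeSkeletonJSONL
#' @export
readSkeletonJSONL <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("N must be >= 1 (file has no frames)")
  frames <- lapply(lines, jsonlite::fromJSON)
  sid <- frames[[1]]$sample_id
  coords <- array(0, dim = c(15L, 3L, length(frames)))
  for (f in seq_along(frames)) {
    j <- frames[[f]]$joints
    miss <- setdiff(jointNames(), names(j))
    if (length(miss) > 0)
      stop(sprintf("frame %d missing joint%s: %s", f,
                   if (length(miss) > 1) "s" else "",
                   paste(miss, collapse = ", ")))
    coords[, , f] <- do.call(rbind, j[jointNames()])
  }
  SkeletonSequence(coords, sampleId = if (is.null(sid)) NA_character_
                   else sid)
}

# KARD per-sample real-world coordinate files list 15 joints per frame in
# the order below; hands map onto the wrist slots and feet onto the ankle
# slots of the canonical numbering.
.kardOrder <- function() {
  # canonical index of the k-th KARD joint
  c(1L, 2L, 3L,            # head, neck, torso
    7L, 8L, 9L,            # right shoulder, right elbow, right hand->wrist
    4L, 5L, 6L,            # left shoulder, left elbow, left hand->wrist
    13L, 14L, 15L,         # right hip, right knee, right foot->ankle
    10L, 11L, 12L)         # left hip, left knee, left foot->ankle
}

#' Read a KARD-style real-world coordinate file
#'
#' Parses the per-sample text files of the Kinect Activity Recognition
#' Dataset: whitespace-separated x y z triples, 15 joints per frame in KARD
#' order (head, neck, torso, then right arm, left arm, right leg, left leg,
#' with hand and foot joints). Joints are remapped onto the canonical
#' numbering (hand -> wrist slot, foot -> ankle slot). Both one-triple-per-
#' line and 45-numbers-per-line layouts are accepted.
#'
#' @param path file path.
#' @param label,subject,viewpoint optional metadata.
#' @return a [SkeletonSequence-class].
#' @export
readKARD <- function(path, label = NA_character_, subject = NA_character_,
                     viewpoint = NA_character_) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) == 0L || length(vals) %% 45L != 0L)
    stop("KARD file must contain 15 joints x 3 coordinates per frame")
  n <- length(vals) %/% 45L
  raw <- array(vals, dim = c(3L, 15L, n))   # coords fastest, then joint
  coords <- array(0, dim = c(15L, 3L, n))
  coords[.kardOrder(), , ] <- aperm(raw, c(2, 1, 3))
  SkeletonSequence(coords, subject = subject, label = label,
                   viewpoint = viewpoint,
                   sampleId = basename(path))
}

#' Export and import an action image as PNG with a JSON sidecar
#'
#' The image is written losslessly as 8-bit RGB, 32 pixels wide by 15 tall;
#' the sidecar \code{<path>.json} records the ordering id and sample
#' metadata so the pairing of rows to joints survives the round trip.
#'
#' @param img an [ActionImage-class].
#' @param path PNG file path.
#' @return \code{readActionImage} returns an [ActionImage-class];
#'   \code{writeActionImage} returns \code{path} invisibly.
#' @export
writeActionImage <- function(img, path) {
  stopifnot(is(img, "ActionImage"))
  png::writePNG(img@pixels / 255, path)
  jsonlite::write_json(
    list(ordering_id = img@orderingId, sample_id = img@sampleId,
         window_start = img@windowStart, label = img@label),
    paste0(path, ".json"), auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeActionImage
#' @export
readActionImage <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) != 3L || dim(px)[3] < 3L ||
      dim(px)[1] != 15L || dim(px)[2] != 32L)
    stop("PNG is not a 15 x 32 RGB action image")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::fromJSON(side) else list()
  pick <- function(x, def) if (is.null(x) || length(x) == 0L) def else x
  new("ActionImage",
      pixels = array(as.integer(round(px[, , 1:3] * 255)), c(15L, 32L, 3L)),
      orderingId = pick(meta$ordering_id, NA_character_),
      sampleId = pick(meta$sample_id, NA_character_),
      windowStart = as.integer(pick(meta$window_start, 0L)),
      label = as.character(pick(meta$label, NA_character_)))
}

#' Write a dataset to disk
#'
#' Writes \code{skeletons.csv} (the skeleton CSV format) and
#' \code{manifest.csv} (\code{sample_id, subject, class, viewpoint}, plus
#' \code{seed} when a generation manifest is supplied) under \code{dir}.
#'
#' @param ds a [LabeledDataset-class] of [SkeletonSequence-class] samples.
#' @param dir output directory (created if needed).
#' @param manifest optional generation manifest from [generateManifest()].
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(ds, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSkeletonCSV(ds, file.path(dir, "skeletons.csv"))
  man <- data.frame(
    sample_id = vapply(ds@samples, sampleId, ""),
    subject = ds@subject, class = ds@label, viewpoint = ds@viewpoint,
    stringsAsFactors = FALSE)
  if (!is.null(manifest))
    man$seed <- manifest$seed[match(man$sample_id, manifest$sample_id)]
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
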