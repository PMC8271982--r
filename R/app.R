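#' Sliding-window classification of a skeleton stream
#'
#' Simulates the real-time pipeline: the stream is cut into 32-frame
#' windows, each window is encoded under the model's joint ordering and
#' classified, and one decision per window is returned in temporal order.
#' A stream shorter than one window yields an empty decision table (with a
#' log message), matching the behavior of a live system that has not yet
#' buffered enough frames.
#'
#' @param stream a [SkeletonSequence-class] of any length.
#' @param model a [TrainedModel-class].
#' @param window window length in frames (default 32).
#' @param stride step between window starts (default 1 frame).
#' @return data.frame with one row per window: \code{windowStart} (0-based),
#'   \code{label}, \code{score}; the full probability matrix is attached as
#'   attribute \code{"probabilities"}.
#' @export
classifyStream <- function(stream, model, window = 32L, stride = 1L) {
  stream <- validateSequence(stream)
  if (is.na(model@orderingId))
    stop("model has no ordering; train it before classifying streams")
  wins <- slidingWindows(stream, length = window, stride = stride)
  if (length(wins) == 0L) {
    out <- data.frame(windowStart = integer(), label = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    attr(out, "probabilities") <-
      matrix(numeric(), 0, length(model@classes),
             dimnames = list(NULL, model@classes))
    return(out)
  }
  imgs <- lapply(wins, encodeSequence, ordering = model@orderingId)
  probs <- predictBatch(model, imgs)
  k <- max.col(probs, ties.method = "first")
  out <- data.frame(
    windowStart = vapply(wins, function(w) w@startFrame, 0L),
    label = model@classes[k],
    score = probs[cbind(seq_along(k), k)],
    stringsAsFactors = FALSE)
  attr(out, "probabilities") <- probs
  out
}

# Recognized configuration keys and their defaults.
.configDefaults <- function() {
  list(data_dir = "data", model_dir = "models", report_dir = "reports",
       ordering = "B1", window_length = 32L, window_stride = 1L,
       epochs = 200L, batch_size = 64L, lr = 0.01, runs = 20L,
       subjects = 32L, frames = 64L, sigma = 0.01, log_level = "info")
}

#' Load a pipeline configuration file
#'
#' Configuration files are YAML mappings validated against a fixed key
#' schema (see \code{system.file("extdata", "config_schema.json",
#' package = "skelact")}); unknown keys are rejected. Missing keys take
#' their documented defaults.
#'
#' @param path YAML file path, or \code{NULL} for the defaults.
#' @return named list of configuration values.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- .configDefaults()
  if (is.null(path)) return(cfg)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key%s: %s (known keys: %s)",
                 if (length(unknown) > 1) "s" else "",
                 paste(unknown, collapse = ", "),
                 paste(names(cfg), collapse = ", ")))
  utils::modifyList(cfg, user)
}

.cliLog <- function(fmt, ...) {
  message(sprintf("[skelact] %s", sprintf(fmt, ...)))
}

.cliFlags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a))
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

.flagOr <- function(flags, key, default) {
  v <- flags[[key]]
  if (is.null(v)) return(default)
  if (is.numeric(default)) as.numeric(v)
  else if (is.integer(default)) as.integer(v)
  else v
}

#' Command-line entry point
#'
#' Drives the full pipeline from the shell; the installed script
#' \code{system.file("cli", "skelact.R", package = "skelact")} forwards
#' \code{commandArgs(TRUE)} here. Commands:
#' \describe{
#'   \item{simulate}{\code{--subjects n --seed s --out dir} (optional
#'     \code{--frames}, \code{--sigma}): write a synthetic dataset with its
#'     manifest.}
#'   \item{encode}{\code{--data dir --ordering id --out dir}: encode every
#'     sample to PNG + JSON sidecar.}
#'   \item{train}{\code{--data dir --ordering id --epochs e --seed s --out
#'     dir}: fit one model on all samples and save a checkpoint.}
#'   \item{evaluate}{\code{--data dir --model dir --out file.json}: write a
#'     run report.}
#'   \item{experiment}{\code{--kind E1|E2 --subjects n --runs r --epochs e
#'     --seed s --out dir} (optional \code{--split a,b,c},
#'     \code{--configs id,id,...}): run a joint-ordering comparison.}
#'   \item{cam}{\code{--model dir --image file.png --out file.png}
#'     (optional \code{--class}): render a class activation map.}
#'   \item{stream}{\code{--model dir --data file.csv --stride k --out
#'     file.csv}: sliding-window classification of a recorded stream.}
#' }
#' Every command honors \code{--seed}, \code{--config} (YAML defaults, see
#' [loadConfig()]) and \code{--out}.
#'
#' @param args character vector of command-line arguments (the first entry
#'   is the command).
#' @return integer exit status, invisibly (0 on success).
#' @export
skelactCLI <- function(args) {
  usage <- paste(
    "usage: skelact <command> [--flags]",
    "commands: simulate | encode | train | evaluate | experiment | cam | stream",
    sep = "\n")
  status <- tryCatch({
    if (length(args) < 1L) stop(usage, call. = FALSE)
    cmd <- args[1]
    flags <- .cliFlags(args[-1])
    cfg <- loadConfig(flags$config)
    seed <- as.integer(.flagOr(flags, "seed", 1))
    out <- flags$out
    switch(cmd,
      simulate = {
        if (is.null(out)) stop("simulate requires --out")
        proto <- collectionProtocol(
          nSubjects = as.integer(.flagOr(flags, "subjects", cfg$subjects)),
          nFrames = as.integer(.flagOr(flags, "frames", cfg$frames)),
          sigma = .flagOr(flags, "sigma", cfg$sigma), seed = seed)
        ds <- generateDataset(proto)
        writeDataset(ds, out, manifest = generateManifest(proto))
        .cliLog("wrote %d samples to %s", length(ds), out)
      },
      encode = {
        if (is.null(flags$data) || is.null(out))
          stop("encode requires --data and --out")
        ord <- getOrdering(.flagOr(flags, "ordering", cfg$ordering))
        ds <- readSkeletonCSV(
          file.path(flags$data, "skeletons.csv"),
          manifest = utils::read.csv(file.path(flags$data, "manifest.csv"),
                                     stringsAsFactors = FALSE))
        imgs <- encodeDataset(ds, ord)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_len(length(imgs)))
          writeActionImage(imgs[[i]],
                           file.path(out, paste0(sampleId(imgs[[i]]),
                                                 ".png")))
        .cliLog("encoded %d images under ordering %s", length(imgs),
                orderingId(ord))
      },
      train = {
        if (is.null(flags$data) || is.null(out))
          stop("train requires --data and --out")
        ord <- .flagOr(flags, "ordering", cfg$ordering)
        ds <- readSkeletonCSV(
          file.path(flags$data, "skeletons.csv"),
          manifest = utils::read.csv(file.path(flags$data, "manifest.csv"),
                                     stringsAsFactors = FALSE))
        imgs <- encodeDataset(ds, ord)
        tc <- trainingConfig(
          epochs = as.integer(.flagOr(flags, "epochs", cfg$epochs)),
          batchSize = as.integer(.flagOr(flags, "batch-size",
                                         cfg$batch_size)),
          lr = .flagOr(flags, "lr", cfg$lr), runs = 1L)
        model <- trainModel(imgs, config = tc, seed = seed)
        saveModel(model, out)
        .cliLog("trained %d epochs; final training accuracy %.1f%%",
                tc$epochs, utils::tail(model@history$accuracy, 1))
      },
      evaluate = {
        if (is.null(flags$data) || is.null(flags$model) || is.null(out))
          stop("evaluate requires --data, --model and --out")
        model <- loadModel(flags$model)
        ds <- readSkeletonCSV(
          file.path(flags$data, "skeletons.csv"),
          manifest = utils::read.csv(file.path(flags$data, "manifest.csv"),
                                     stringsAsFactors = FALSE))
        rep <- evaluateModel(model, encodeDataset(ds, model@orderingId))
        jsonlite::write_json(
          list(seed = rep@seed, accuracy = rep@accuracy,
               per_class = as.list(rep@perClass), mcc = rep@mcc,
               ordering = rep@orderingId,
               confusion = unname(apply(rep@confusion, 1, as.list))),
          out, auto_unbox = TRUE, digits = NA, na = "null")
        .cliLog("accuracy %.1f%%, MCC %.1f%%", rep@accuracy, rep@mcc)
      },
      experiment = {
        if (is.null(out)) stop("experiment requires --out")
        proto <- collectionProtocol(
          nSubjects = as.integer(.flagOr(flags, "subjects", cfg$subjects)),
          nFrames = as.integer(.flagOr(flags, "frames", cfg$frames)),
          sigma = .flagOr(flags, "sigma", cfg$sigma), seed = seed)
        ds <- generateDataset(proto)
        tc <- trainingConfig(
          epochs = as.integer(.flagOr(flags, "epochs", cfg$epochs)),
          runs = as.integer(.flagOr(flags, "runs", cfg$runs)))
        split <- if (!is.null(flags$split))
          as.integer(strsplit(flags$split, ",")[[1]])
        else {
          n <- proto$nSubjects
          c(n - 2L * max(1L, n %/% 5L), max(1L, n %/% 5L),
            max(1L, n %/% 5L))
        }
        configs <- if (!is.null(flags$configs))
          strsplit(flags$configs, ",")[[1]] else NULL
        repx <- runExperiment(.flagOr(flags, "kind", "E1"), ds,
                              config = tc, split = split, seed = seed,
                              configs = configs)
        writeExperimentReport(repx, out)
        .cliLog("experiment %s: %d configurations x %d runs", repx@kind,
                length(repx@configIds), tc$runs)
      },
      cam = {
        if (is.null(flags$model) || is.null(flags$image) || is.null(out))
          stop("cam requires --model, --image and --out")
        model <- loadModel(flags$model)
        img <- readActionImage(flags$image)
        cam <- classActivationMap(model, img,
                                  class = flags[["class"]])
        png::writePNG(cam$map, out)
        jsonlite::write_json(
          list(class = cam$class,
               score = unname(cam$probabilities[cam$class])),
          paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
        .cliLog("CAM for class %s (score %.2f)", cam$class,
                cam$probabilities[cam$class])
      },
      stream = {
        if (is.null(flags$model) || is.null(flags$data) || is.null(out))
          stop("stream requires --model, --data and --out")
        model <- loadModel(flags$model)
        ds <- readSkeletonCSV(flags$data)
        t0 <- proc.time()[3]
        dec <- classifyStream(ds[[1]], model,
                              stride = as.integer(.flagOr(flags, "stride",
                                                          cfg$window_stride)))
        dt <- proc.time()[3] - t0
        utils::write.csv(dec, out, row.names = FALSE)
        .cliLog("%d decisions in %.2f s (informational timing only)",
                nrow(dec), dt)
      },
      stop(usage, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
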