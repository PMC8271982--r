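#' Save and load a trained model
#'
#' A model checkpoint is a directory holding the learned parameters in R's
#' native serialization (\code{params.rds}), a JSON manifest with the label
#' vocabulary, joint-ordering id, seed and training configuration, and the
#' per-epoch training history as CSV.
#'
#' @param model a [TrainedModel-class].
#' @param dir checkpoint directory (created if needed).
#' @return \code{saveModel} returns \code{dir} invisibly; \code{loadModel}
#'   returns a [TrainedModel-class].
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model@params, file.path(dir, "params.rds"))
  jsonlite::write_json(
    list(classes = model@classes, ordering_id = model@orderingId,
         seed = model@seed, config = model@config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  utils::write.csv(model@history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  params <- readRDS(file.path(dir, "params.rds"))
  meta <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  hist <- utils::read.csv(file.path(dir, "history.csv"))
  ord <- meta$ordering_id
  new("TrainedModel", params = params,
      classes = as.character(meta$classes),
      orderingId = if (is.null(ord)) NA_character_ else as.character(ord),
      history = hist, seed = as.integer(meta$seed),
      config = as.list(meta$config))
}
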