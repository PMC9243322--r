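# Checkpointing: serialized parameters plus a JSON sidecar recording the
# architecture name and class order, so a checkpoint can be sanity-checked
# without deserializing it.

#' Save a model checkpoint
#'
#' Writes the model to `<path>.rds` (R's standard serialized format) and
#' a JSON sidecar `<path>.json` recording the model class, backbone
#' name(s) and the class order.
#'
#' @param model a [BaseClassifier-class], [WeightFusionModel-class] or
#'   [AutoFusionModel-class].
#' @param path checkpoint path without extension.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot2(is(model, "BaseClassifier") || is(model, "WeightFusionModel")
             || is(model, "AutoFusionModel"),
             "model must be a classifier or fusion model")
  backboneNames <- if (is(model, "BaseClassifier")) model@name
    else if (is(model, "WeightFusionModel"))
      vapply(model@classifiers, slot, character(1), "name")
    else vapply(model@backbones, slot, character(1), "name")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, paste0(path, ".rds"))
  jsonlite::write_json(list(modelClass = class(model)[1],
                            backbones = backboneNames,
                            classNames = classNames(model)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Reads `<path>.rds` and verifies it against the JSON sidecar written
#' by [saveCheckpoint()].
#'
#' @param path checkpoint path without extension.
#' @return the deserialized model.
#' @export
loadCheckpoint <- function(path) {
  rds <- paste0(path, ".rds")
  stopifnot2(file.exists(rds), paste("no checkpoint at", rds))
  model <- readRDS(rds)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!identical(meta$modelClass, class(model)[1]) ||
        !identical(as.character(meta$classNames), classNames(model)))
      stop("checkpoint sidecar does not match the serialized model",
           call. = FALSE)
  }
  model
}
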