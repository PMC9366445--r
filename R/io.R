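#' Serialise a trained model to a portable JSON container
#'
#' Writes the network specification, the training configuration (including
#' both seeds and a config digest) and all weight tensors to one JSON file
#' at full double precision, so a model can be reloaded bit-faithfully on
#' any platform.
#'
#' @param model A [train_contrast_cnn()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(model, path) {
  payload <- list(
    format = "morphocontrast-weights-v1",
    spec = unclass(model$spec),
    config = unclass(model$config),
    config_digest = config_digest(unclass(model$config)),
    group_levels = model$group_levels,
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), values = as.numeric(w))
      else list(dim = length(w), values = as.numeric(w))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a model serialised by [write_weights()]
#'
#' @param path JSON file path.
#' @return A `contrast_cnn` object (without a training log or training-set
#'   scores; suitable for [embed_set()] and [classify_nearest_centroid()]).
#' @export
read_weights <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "morphocontrast-weights-v1")) {
    abort("not a morphocontrast weights file.",
          class = "morphocontrast_format_error")
  }
  spec <- payload$spec
  spec[] <- lapply(spec, function(v) if (is.numeric(v)) as.integer(v) else v)
  spec$pool <- as.character(payload$spec$pool)
  class(spec) <- "network_spec"
  weights <- lapply(payload$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$values, w$dim[1], w$dim[2])
    else as.numeric(w$values)
  })
  cfg <- payload$config
  class(cfg) <- "train_config"
  structure(list(weights = weights, spec = spec, config = cfg,
                 group_levels = payload$group_levels),
            class = "contrast_cnn")
}

#' Export a contrast table to CSV
#'
#' Writes `id_a,id_b,same_group,distance`; distances are computed first via
#' [contrast_distances()] when an image set is supplied.
#'
#' @param contrasts Tibble from [enumerate_contrasts()].
#' @param path Output CSV path.
#' @param images Optional image manifest used to fill the `distance` column.
#' @return The exported tibble, invisibly.
#' @export
write_contrasts <- function(contrasts, path, images = NULL) {
  if (!is.null(images)) contrasts <- contrast_distances(contrasts, images)
  if (!"distance" %in% names(contrasts)) contrasts$distance <- NA_real_
  readr::write_csv(contrasts[, c("id_a", "id_b", "same_group", "distance")],
                   path)
  invisible(contrasts)
}

#' Export feature-space scores to CSV
#'
#' @param scores A `feature_space` tibble from [embed_set()].
#' @param path Output CSV path (`specimen_id,group,score_1..score_k`).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(as_tibble(scores), path)
  invisible(path)
}

#' Export a confusion matrix to CSV with labelled rows and columns
#'
#' @param cm A [confusion_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  df <- as.data.frame.matrix(unclass(cm))
  df <- cbind(truth = rownames(df), df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}
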