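#' Build a confusion matrix from truth and assignment vectors
#'
#' @param truth,predicted Label vectors of equal length.
#' @param labels Ordered label set (default: sorted union of both vectors).
#' @return Object of class `confusion_matrix`: a g x g integer count table,
#'   rows = true group, columns = assigned group.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  if (length(truth) != length(predicted) || length(truth) == 0L) {
    abort("`truth` and `predicted` must be non-empty and equal length.",
          class = "morphocontrast_config_error")
  }
  labels <- labels %||% sort(union(truth, predicted))
  counts <- table(factor(truth, levels = labels),
                  factor(predicted, levels = labels))
  structure(unclass(counts), class = "confusion_matrix",
            dimnames = list(truth = labels, assigned = labels))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, n = %d, accuracy %.4f\n",
              nrow(x), sum(x), accuracy(x)))
  print(unclass(x))
  invisible(x)
}

#' Raw identification accuracy of a confusion matrix
#'
#' @param cm A [confusion_matrix()].
#' @return `trace / n`.
#' @export
accuracy <- function(cm) {
  sum(diag(cm)) / sum(cm)
}

#' Multiclass Matthews correlation coefficient
#'
#' Chance-corrected accuracy index computed from the full confusion matrix
#' (the covariance form, which reduces to the classic binary MCC formula on
#' 2 x 2 tables): 1 = perfect agreement, 0 = chance level, -1 = total
#' disagreement.  When a marginal is degenerate (e.g. every specimen
#' assigned to one class) the denominator vanishes and 0 is returned with a
#' warning.
#'
#' @param cm A [confusion_matrix()] (any non-negative g x g count matrix).
#' @return Scalar in \[-1, 1\].
#' @export
mcc <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n < 1) {
    abort("empty confusion matrix.", class = "morphocontrast_config_error")
  }
  correct <- sum(diag(cm))
  t_k <- rowSums(cm)  # true-class totals
  p_k <- colSums(cm)  # assigned-class totals
  num <- correct * n - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  if (den == 0) {
    warn("degenerate marginal in confusion matrix; MCC set to 0.")
    return(0)
  }
  num / den
}

#' Post-hoc identification of the training set
#'
#' Embeds the training images with the trained network, assigns each to the
#' nearest group centroid, and tabulates assignments against the manifest's
#' true groups -- the first-stage performance check of a trained
#' discrimination system.
#'
#' @param model A trained [train_contrast_cnn()] object.
#' @param images The training manifest tibble with `pixels` (defaults to
#'   requiring the caller to pass the same set the model was trained on).
#' @return Object of class `identification_result`: `assignments` tibble,
#'   `confusion` matrix, `accuracy`, `mcc`.
#' @export
post_hoc_identify <- function(model, images) {
  images <- as_tibble(images)
  if (!setequal(unique(images$group), model$group_levels)) {
    abort("image groups do not match the groups the model was trained on.",
          class = "morphocontrast_model_error")
  }
  fs <- embed_set(model, images)
  cls <- classify_nearest_centroid(fs, model$centroids)
  cm <- confusion_matrix(images$group, cls$assigned,
                         labels = model$group_levels)
  structure(
    list(assignments = dplyr::bind_cols(images[, "specimen_id"],
                                        truth = images$group,
                                        cls[, c("assigned", "tie", "distance")]),
         confusion = cm, accuracy = accuracy(cm), mcc = mcc(cm)),
    class = "identification_result"
  )
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification_result> n = %d, accuracy %.4f, MCC %.4f\n",
              sum(x$confusion), x$accuracy, x$mcc))
  invisible(x)
}

#' @method glance identification_result
#' @export
glance.identification_result <- function(x, ...) {
  tibble(n = sum(x$confusion), accuracy = x$accuracy, mcc = x$mcc)
}

#' Sequester-and-retrain jackknife validation
#'
#' The cross-tabulation stability check for small samples: `n_holdout`
#' specimens are selected at random; each in turn is sequestered, the
#' network is retrained from scratch on all remaining specimens under an
#' identical configuration, and the holdout is classified by nearest
#' centroid in the retrained feature space.  Assignments are aggregated into
#' one validation confusion matrix.
#'
#' @param images Prepared manifest tibble with `pixels`.
#' @param n_holdout Number of validation specimens (0 gives an empty
#'   report without retraining).
#' @param config A [train_config()] used for every retraining; only the
#'   training-set composition changes between iterations.
#' @param seed Integer seed for the holdout selection.
#' @return Object of class `jackknife_report`: `holdout_ids`, per-holdout
#'   `assignments` (with truth, tie flag and a `group_trained` flag that is
#'   `FALSE` when sequestration emptied the specimen's group), aggregate
#'   `confusion`, `accuracy`, `mcc`, `missing_groups` (groups absent from
#'   the validation cohort) and the seeds used.
#' @export
jackknife <- function(images, n_holdout = 40, config = train_config(),
                      seed = 1L) {
  images <- as_tibble(images)
  n <- nrow(images)
  if (!is_count(n_holdout, 0L) || n_holdout >= n) {
    abort("`n_holdout` must be a count smaller than the number of specimens.",
          class = "morphocontrast_config_error")
  }
  if (n_holdout == 0L) {
    return(structure(list(holdout_ids = character(),
                          assignments = tibble(), confusion = NULL,
                          accuracy = NA_real_, mcc = NA_real_,
                          missing_groups = sort(unique(images$group)),
                          seed = as.integer(seed), config = config),
                     class = "jackknife_report"))
  }
  holdout_ids <- with_seed(substream_seed(seed, 1L),
                           sample(images$specimen_id, n_holdout))
  rows <- vector("list", n_holdout)
  for (i in seq_along(holdout_ids)) {
    hid <- holdout_ids[i]
    train_set <- images[images$specimen_id != hid, ]
    holdout <- images[images$specimen_id == hid, ]
    group_trained <- holdout$group %in% train_set$group
    if (!group_trained) {
      rows[[i]] <- tibble(specimen_id = hid, truth = holdout$group,
                          assigned = NA_character_, tie = NA,
                          group_trained = FALSE)
      next
    }
    model <- train_contrast_cnn(train_set, config)
    fs <- embed_set(model, holdout)
    cls <- classify_nearest_centroid(fs, model$centroids)
    rows[[i]] <- tibble(specimen_id = hid, truth = holdout$group,
                        assigned = cls$assigned, tie = cls$tie,
                        group_trained = TRUE)
  }
  assignments <- dplyr::bind_rows(rows)
  scored <- assignments[assignments$group_trained, ]
  if (nrow(scored) > 0L) {
    cm <- confusion_matrix(scored$truth, scored$assigned,
                           labels = sort(unique(images$group)))
  } else {
    cm <- NULL
  }
  structure(
    list(holdout_ids = holdout_ids, assignments = assignments,
         confusion = cm,
         accuracy = if (is.null(cm)) NA_real_ else accuracy(cm),
         mcc = if (is.null(cm)) NA_real_ else mcc(cm),
         missing_groups = setdiff(sort(unique(images$group)),
                                  unique(assignments$truth)),
         seed = as.integer(seed), config = config),
    class = "jackknife_report"
  )
}

#' @export
print.jackknife_report <- function(x, ...) {
  if (length(x$holdout_ids) == 0L) {
    cat("<jackknife_report> empty (n_holdout = 0)\n")
    return(invisible(x))
  }
  cat(sprintf("<jackknife_report> %d holdouts, accuracy %.4f, MCC %.4f\n",
              length(x$holdout_ids), x$accuracy, x$mcc))
  if (length(x$missing_groups)) {
    cat("  groups absent from validation cohort:",
        paste(x$missing_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy jackknife_report
#' @export
tidy.jackknife_report <- function(x, ...) x$assignments

#' @method glance jackknife_report
#' @export
glance.jackknife_report <- function(x, ...) {
  tibble(n_holdout = length(x$holdout_ids), accuracy = x$accuracy,
         mcc = x$mcc, n_missing_groups = length(x$missing_groups),
         seed = x$seed)
}
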