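#' Margin-based contrastive loss
#'
#' For a pair of embeddings at Euclidean distance `d`, same-group pairs
#' contribute `d^2` (pulling group members together) and different-group
#' pairs contribute `max(0, margin - d)^2` (pushing non-members at least
#' `margin` apart) -- the canonical realisation of maximising between-group
#' and minimising within-group image distances.
#'
#' @param emb_a,emb_b Embedding vectors, or n x k matrices of embeddings.
#' @param same_group Logical (vector) pair label(s).
#' @param margin Positive margin for different-group pairs (default 1).
#' @return Per-pair non-negative loss (scalar or vector).
#' @examples
#' contrastive_loss(c(0, 0), c(0.4, 0), FALSE)  # (1 - 0.4)^2 = 0.36
#' @export
contrastive_loss <- function(emb_a, emb_b, same_group, margin = 1) {
  if (is.null(dim(emb_a))) emb_a <- matrix(emb_a, nrow = 1)
  if (is.null(dim(emb_b))) emb_b <- matrix(emb_b, nrow = 1)
  if (!identical(dim(emb_a), dim(emb_b))) {
    abort("embeddings must have identical dimensions.",
          class = "morphocontrast_dimension_error")
  }
  stopifnot_scalar_number(margin, "margin", min = 0, allow_zero = FALSE)
  d <- sqrt(rowSums((emb_a - emb_b)^2))
  ifelse(same_group, d^2, pmax(0, margin - d)^2)
}

# Loss gradients with respect to both embeddings; returns list(dA, dB) of
# the same shapes, averaged over the batch by the caller.
contrastive_loss_grad <- function(emb_a, emb_b, same_group, margin = 1) {
  delta <- emb_a - emb_b
  d <- sqrt(rowSums(delta^2))
  coef <- ifelse(same_group, 2,
                 ifelse(d < margin & d > 1e-12, -2 * (margin - d) / d, 0))
  dA <- delta * coef
  list(dA = dA, dB = -dA)
}

#' Training configuration for the contrast network
#'
#' @param n_rounds Training rounds / epochs (default 10).
#' @param batch_size Contrasts per batch (default 64).
#' @param embed_dim Embedding dimension (default 2).
#' @param margin Contrastive-loss margin (default 1).
#' @param learning_rate Optimiser step size (default 1e-3).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param pairs_per_round Contrasts presented per round.  `NULL` (default)
#'   presents every unordered pair once per round; a smaller count draws a
#'   seeded subsample each round.
#' @param balanced Draw equal numbers of same- and different-group pairs per
#'   round (default `TRUE`; same-group pairs are a small minority of all
#'   pairs, so balancing resamples them).
#' @param init_seed,shuffle_seed Integer seeds for weight initialisation and
#'   pair ordering; recorded in every results object.
#' @return Object of class `train_config`.
#' @export
train_config <- function(n_rounds = 10, batch_size = 64, embed_dim = 2,
                         margin = 1, learning_rate = 1e-3,
                         optimizer = c("adam", "sgd"),
                         pairs_per_round = NULL, balanced = TRUE,
                         init_seed = 1L, shuffle_seed = 2L) {
  optimizer <- match.arg(optimizer)
  if (!is_count(n_rounds, 1L) || !is_count(batch_size, 1L) ||
      !is_count(embed_dim, 1L)) {
    abort("`n_rounds`, `batch_size` and `embed_dim` must be positive counts.",
          class = "morphocontrast_config_error")
  }
  stopifnot_scalar_number(margin, "margin", min = 0, allow_zero = FALSE)
  stopifnot_scalar_number(learning_rate, "learning_rate", min = 0,
                          allow_zero = FALSE)
  if (!is.null(pairs_per_round) && !is_count(pairs_per_round, 2L)) {
    abort("`pairs_per_round` must be NULL or a count >= 2.",
          class = "morphocontrast_config_error")
  }
  structure(
    list(n_rounds = as.integer(n_rounds), batch_size = as.integer(batch_size),
         embed_dim = as.integer(embed_dim), margin = margin,
         learning_rate = learning_rate, optimizer = optimizer,
         pairs_per_round = pairs_per_round, balanced = isTRUE(balanced),
         init_seed = as.integer(init_seed),
         shuffle_seed = as.integer(shuffle_seed)),
    class = "train_config"
  )
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

#' Train the embedded group-contrast network
#'
#' Runs the Siamese training loop: every batch presents `batch_size` image
#' contrasts, both images of a pair pass through one shared-weight network,
#' and the margin-based contrastive loss is backpropagated.  Pair order is
#' reshuffled between rounds under seeded substreams, so identical seeds and
#' configuration reproduce identical weights and logs.
#'
#' @param images Prepared manifest tibble (see [prep_images()]) with columns
#'   `specimen_id`, `group` and a `pixels` list-column of
#'   `input_size` x `input_size` matrices in \[0, 1\].
#' @param config A [train_config()].
#' @param spec A [network_spec()]; defaults to the standard spec with
#'   `config$embed_dim` output dimensions.
#' @return Object of class `contrast_cnn`: trained `weights`, `spec`,
#'   `config`, a training `log` tibble (`round`, `batch`, `loss`,
#'   `train_error`; the nearest-centroid training error is evaluated at the
#'   end of each round), the training manifest, and the final feature-space
#'   `scores` and `centroids`.
#' @export
train_contrast_cnn <- function(images, config = train_config(),
                               spec = NULL) {
  images <- as_tibble(images)
  if (is.null(spec)) spec <- network_spec(embed_dim = config$embed_dim)
  if (spec$embed_dim != config$embed_dim) {
    abort("`spec$embed_dim` disagrees with `config$embed_dim`.",
          class = "morphocontrast_model_error")
  }
  tab <- table(images$group)
  if (length(tab) < 2L || any(tab < 2L)) {
    abort("training requires >= 2 groups with >= 2 specimens each.",
          class = "morphocontrast_config_error")
  }
  X <- image_matrix(images)
  contrasts <- enumerate_contrasts(images)
  ia_all <- match(contrasts$id_a, images$specimen_id)
  ib_all <- match(contrasts$id_b, images$specimen_id)
  same_all <- contrasts$same_group
  n_pairs <- length(ia_all)
  per_round <- config$pairs_per_round %||% n_pairs

  weights <- init_weights(spec, config$init_seed)
  state <- if (config$optimizer == "adam") adam_init(weights) else NULL
  log_rows <- list()

  for (r in seq_len(config$n_rounds)) {
    round_idx <- with_seed(substream_seed(config$shuffle_seed, r), {
      if (config$balanced) {
        same <- which(same_all)
        diff <- which(!same_all)
        ns <- floor(per_round / 2)
        sample(c(sample(same, ns, replace = ns > length(same)),
                 sample(diff, per_round - ns,
                        replace = (per_round - ns) > length(diff))))
      } else if (per_round < n_pairs) {
        sample(n_pairs, per_round)
      } else {
        sample.int(n_pairs)
      }
    })
    n_batches <- ceiling(length(round_idx) / config$batch_size)
    losses <- numeric(n_batches)
    for (bi in seq_len(n_batches)) {
      take <- round_idx[((bi - 1L) * config$batch_size + 1L):
                          min(bi * config$batch_size, length(round_idx))]
      ia <- ia_all[take]
      ib <- ib_all[take]
      same <- same_all[take]
      B <- length(take)
      fwd <- nn_forward_batch(weights, spec,
                              X[c(ia, ib), , drop = FALSE],
                              keep_cache = TRUE)
      ea <- fwd$emb[seq_len(B), , drop = FALSE]
      eb <- fwd$emb[B + seq_len(B), , drop = FALSE]
      loss <- mean(contrastive_loss(ea, eb, same, config$margin))
      if (!is.finite(loss)) {
        abort(sprintf("non-finite loss in round %d, batch %d.", r, bi),
              class = "morphocontrast_divergence_error")
      }
      g <- contrastive_loss_grad(ea, eb, same, config$margin)
      dE <- rbind(g$dA, g$dB) / B
      grads <- nn_backward_batch(weights, spec, fwd$cache, dE)
      if (config$optimizer == "adam") {
        upd <- adam_step(weights, grads, state, config$learning_rate)
        weights <- upd$weights
        state <- upd$state
      } else {
        for (nm in names(weights)) {
          weights[[nm]] <- weights[[nm]] - config$learning_rate * grads[[nm]]
        }
      }
      losses[bi] <- loss
    }
    err <- training_error(weights, spec, X, images$group)
    log_rows[[r]] <- tibble(round = r, batch = seq_len(n_batches),
                            loss = losses,
                            train_error = c(rep(NA_real_, n_batches - 1L), err))
  }

  model <- structure(
    list(weights = weights, spec = spec, config = config,
         log = dplyr::bind_rows(log_rows),
         manifest = images[, setdiff(names(images), "pixels")],
         group_levels = sort(unique(images$group))),
    class = "contrast_cnn"
  )
  fs <- embed_set(model, images)
  model$scores <- fs
  model$centroids <- attr(fs, "centroids")
  model
}

# Nearest-centroid misassignment rate on the training set.
training_error <- function(weights, spec, X, groups) {
  E <- embed_in_chunks(weights, spec, X)
  cent <- rowsum(E, groups) / as.vector(table(groups)[sort(unique(groups))])
  d2 <- outer(rowSums(E^2), rowSums(cent^2), `+`) - 2 * E %*% t(cent)
  pred <- rownames(cent)[max.col(-d2, ties.method = "first")]
  mean(pred != groups)
}

embed_in_chunks <- function(weights, spec, X, chunk = 512L) {
  n <- nrow(X)
  out <- matrix(0, n, spec$embed_dim)
  for (s in seq(1L, n, by = chunk)) {
    e <- s:min(s + chunk - 1L, n)
    out[e, ] <- nn_forward_batch(weights, spec, X[e, , drop = FALSE])$emb
  }
  out
}

#' @export
print.contrast_cnn <- function(x, ...) {
  cat("<contrast_cnn>\n")
  cat(sprintf("  %d specimens, %d groups; embed_dim %d; %d rounds trained\n",
              nrow(x$manifest), length(x$group_levels), x$spec$embed_dim,
              max(x$log$round)))
  fin <- x$log$train_error[!is.na(x$log$train_error)]
  cat(sprintf("  final mean batch loss %.4g; final training error %.4g\n",
              mean(x$log$loss[x$log$round == max(x$log$round)]),
              fin[length(fin)]))
  invisible(x)
}

#' @method tidy contrast_cnn
#' @export
tidy.contrast_cnn <- function(x, ...) x$log

#' @method glance contrast_cnn
#' @export
glance.contrast_cnn <- function(x, ...) {
  fin <- x$log$train_error[!is.na(x$log$train_error)]
  tibble(n_specimens = nrow(x$manifest),
         n_groups = length(x$group_levels),
         embed_dim = x$spec$embed_dim,
         n_rounds = max(x$log$round),
         n_parameters = n_params(x$spec),
         final_loss = mean(x$log$loss[x$log$round == max(x$log$round)]),
         final_train_error = fin[length(fin)],
         init_seed = x$config$init_seed,
         shuffle_seed = x$config$shuffle_seed)
}

#' @export
predict.contrast_cnn <- function(object, newdata, ...) {
  embed_set(object, newdata)
}

#' Embed an image set into the trained feature space
#'
#' @param model A trained [train_contrast_cnn()] object.
#' @param images Prepared manifest tibble with a `pixels` list-column.
#' @return A `feature_space` tibble: `specimen_id`, `group`, `substrate` (if
#'   present) and score columns `score_1..score_k`, with the per-group
#'   centroid table attached as attribute `"centroids"` (also via
#'   [group_centroids()]).
#' @export
embed_set <- function(model, images) {
  images <- as_tibble(images)
  X <- image_matrix(images)
  E <- embed_in_chunks(model$weights, model$spec, X)
  colnames(E) <- paste0("score_", seq_len(ncol(E)))
  out <- dplyr::bind_cols(
    images[, intersect(c("specimen_id", "group", "substrate"), names(images))],
    as_tibble(E)
  )
  class(out) <- c("feature_space", class(out))
  attr(out, "centroids") <- group_centroids(out)
  out
}

#' Per-group centroids of a feature space
#'
#' @param scores A `feature_space` tibble (or any data frame with a `group`
#'   column and `score_*` columns).
#' @return Tibble with one row per group: `group`, `score_1..score_k`.
#' @export
group_centroids <- function(scores) {
  sc <- as_tibble(scores)[, c("group", grep("^score_", names(scores),
                                            value = TRUE))]
  dplyr::summarise(dplyr::group_by(sc, .data$group),
                   dplyr::across(dplyr::starts_with("score_"), mean),
                   .groups = "drop") |>
    dplyr::arrange(.data$group)
}

#' Nearest-centroid classification in the feature space
#'
#' Assigns each query score vector to the group whose centroid is nearest in
#' Euclidean distance (the typical decision criterion in a trained feature
#' space).  Exact ties are broken toward the lexicographically first group
#' label and flagged.
#'
#' @param queries A `feature_space` tibble, or a matrix/data frame of score
#'   columns.
#' @param centroids Centroid tibble from [group_centroids()] (taken from the
#'   `queries` attribute when omitted).
#' @return Tibble with `specimen_id` (if available), `assigned`, `tie`, and
#'   the distance to the winning centroid.
#' @export
classify_nearest_centroid <- function(queries, centroids = NULL) {
  centroids <- centroids %||% attr(queries, "centroids")
  if (is.null(centroids) || nrow(centroids) == 0L) {
    abort("no centroids supplied.", class = "morphocontrast_model_error")
  }
  centroids <- dplyr::arrange(as_tibble(centroids), .data$group)
  score_cols <- grep("^score_", names(centroids), value = TRUE)
  if (is.matrix(queries)) {
    Q <- queries
    ids <- NULL
  } else {
    Q <- as.matrix(as_tibble(queries)[, score_cols])
    ids <- as_tibble(queries)[["specimen_id"]]
  }
  C <- as.matrix(centroids[, score_cols])
  d2 <- outer(rowSums(Q^2), rowSums(C^2), `+`) - 2 * Q %*% t(C)
  d2 <- pmax(d2, 0)
  best <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(Q)), best)])
  tie <- vapply(seq_len(nrow(Q)), function(i) {
    sum(abs(d2[i, ] - d2[i, best[i]]) < 1e-12) > 1L
  }, logical(1))
  out <- tibble(assigned = centroids$group[best], tie = tie, distance = dmin)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble(specimen_id = ids), out)
  out
}
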