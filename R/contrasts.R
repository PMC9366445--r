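#' Enumerate all pairwise image contrasts in a manifest
#'
#' Builds the group-contrast training material: every pair of specimens,
#' labelled `same_group` from the manifest's group column.  With `ordered =
#' TRUE` all `n(n-1)` ordered pairs are produced (the convention under which
#' 386 specimens give 148,610 contrasts); the default enumerates the
#' `n(n-1)/2` unordered pairs, sufficient for a symmetric contrastive loss.
#'
#' @param manifest Data frame with columns `specimen_id` and `group`.
#' @param ordered Enumerate ordered pairs? Default `FALSE`.
#' @return Tibble with columns `id_a`, `id_b`, `same_group`.
#' @examples
#' m <- tibble::tibble(specimen_id = letters[1:4],
#'                     group = c("x", "x", "y", "y"))
#' nrow(enumerate_contrasts(m))            # 6
#' nrow(enumerate_contrasts(m, ordered = TRUE))  # 12
#' @export
enumerate_contrasts <- function(manifest, ordered = FALSE) {
  manifest <- as_tibble(manifest)
  n <- nrow(manifest)
  if (n < 2L) {
    abort("at least 2 specimens are required to form contrasts.",
          class = "morphocontrast_manifest_error")
  }
  if (anyDuplicated(manifest$specimen_id)) {
    abort("manifest contains duplicate specimen ids.",
          class = "morphocontrast_manifest_error")
  }
  idx <- utils::combn(n, 2L)
  a <- idx[1L, ]
  b <- idx[2L, ]
  if (ordered) {
    a2 <- c(a, b)
    b2 <- c(b, a)
    a <- a2
    b <- b2
  }
  tibble(
    id_a = manifest$specimen_id[a],
    id_b = manifest$specimen_id[b],
    same_group = manifest$group[a] == manifest$group[b]
  )
}

#' Euclidean distance between two images
#'
#' The image distance `d`: the Euclidean norm of the flattened pixel-wise
#' difference between two equal-shape images.
#'
#' @param a,b Numeric matrices of identical shape.
#' @return Non-negative scalar; 0 iff the images are pixel-identical.
#' @export
image_distance <- function(a, b) {
  a <- as_pixel_matrix(a, "a")
  b <- as_pixel_matrix(b, "b")
  if (!identical(dim(a), dim(b))) {
    abort("images must have identical dimensions.",
          class = "morphocontrast_dimension_error")
  }
  sqrt(sum((a - b)^2))
}

#' Per-pixel difference image
#'
#' The absolute pixel-wise difference between two images, by default rendered
#' inverted so that regions of high difference appear dark on a light
#' background (the convention used to visualise image contrasts).
#'
#' @param a,b Numeric matrices of identical shape, values in \[0, 1\].
#' @param invert Render large differences dark? Default `TRUE`.
#' @return Matrix in \[0, 1\].
#' @export
difference_image <- function(a, b, invert = TRUE) {
  a <- as_pixel_matrix(a, "a")
  b <- as_pixel_matrix(b, "b")
  if (!identical(dim(a), dim(b))) {
    abort("images must have identical dimensions.",
          class = "morphocontrast_dimension_error")
  }
  d <- abs(a - b)
  if (invert) 1 - d else d
}

#' Attach image distances to a contrast table
#'
#' @param contrasts Tibble from [enumerate_contrasts()].
#' @param images Manifest tibble with `specimen_id` and a prepared `pixels`
#'   list-column.
#' @return `contrasts` with a numeric `distance` column appended.
#' @export
contrast_distances <- function(contrasts, images) {
  x <- image_matrix(images)
  ia <- match(contrasts$id_a, images$specimen_id)
  ib <- match(contrasts$id_b, images$specimen_id)
  if (anyNA(ia) || anyNA(ib)) {
    abort("contrast ids missing from the image manifest.",
          class = "morphocontrast_manifest_error")
  }
  d2 <- rowSums((x[ia, , drop = FALSE] - x[ib, , drop = FALSE])^2)
  dplyr::mutate(contrasts, distance = sqrt(d2))
}

# Flatten an image-set tibble into an n x (h*w) matrix of unit-scaled pixels.
image_matrix <- function(images) {
  px <- purrr::map(images$pixels, to_unit_range)
  t(vapply(px, as.numeric, numeric(length(px[[1]]))))
}

#' Subsample a contrast list
#'
#' Draws a seeded subsample of contrasts, optionally balanced so that
#' same-group and different-group pairs appear in equal numbers (same-group
#' pairs are a small minority of all pairs, so balancing samples them with
#' replacement when necessary).
#'
#' @param contrasts Tibble from [enumerate_contrasts()].
#' @param n Number of contrasts to draw.
#' @param balanced Draw `n/2` same-group and `n/2` different-group pairs?
#'   Default `TRUE`.
#' @param seed Integer seed.
#' @return Tibble of `n` contrast rows.
#' @export
subsample_contrasts <- function(contrasts, n, balanced = TRUE, seed = 1L) {
  if (!is_count(n, min = 1L)) {
    abort("`n` must be a positive count.",
          class = "morphocontrast_config_error")
  }
  with_seed(seed, {
    if (balanced) {
      same <- which(contrasts$same_group)
      diff <- which(!contrasts$same_group)
      if (length(same) == 0L || length(diff) == 0L) {
        abort("balanced subsampling needs both same- and different-group pairs.",
              class = "morphocontrast_config_error")
      }
      n_same <- floor(n / 2)
      pick <- c(sample(same, n_same, replace = n_same > length(same)),
                sample(diff, n - n_same, replace = (n - n_same) > length(diff)))
      contrasts[sample(pick), ]
    } else {
      contrasts[sample(nrow(contrasts), min(n, nrow(contrasts))), ]
    }
  })
}

#' Plan seeded training batches over a contrast list
#'
#' Cuts the contrast list into batches of `batch_size` for each training
#' round; within a round every contrast appears exactly once, the order is a
#' seeded permutation, and the permutation changes between rounds (the
#' "shuffled randomly between rounds" regime: e.g. 119,232 contrasts in
#' batches of 64 give 1863 batches per round, and 10 rounds present
#' 1,192,320 contrasts in total).
#'
#' @param n_contrasts Number of contrasts (or a contrast tibble, whose row
#'   count is used).
#' @param batch_size Contrasts per batch (default 64).
#' @param n_rounds Training rounds / epochs (default 10).
#' @param shuffle_seed Integer seed.
#' @return Object of class `batch_plan`: a list with one element per round,
#'   each a list of integer index vectors (the final batch may be short).
#' @export
plan_batches <- function(n_contrasts, batch_size = 64, n_rounds = 10,
                         shuffle_seed = 1L) {
  if (is.data.frame(n_contrasts)) n_contrasts <- nrow(n_contrasts)
  if (!is_count(n_contrasts, min = 1L)) {
    abort("contrast list must be non-empty.",
          class = "morphocontrast_config_error")
  }
  if (!is_count(batch_size, min = 1L)) {
    abort("`batch_size` must be >= 1.",
          class = "morphocontrast_config_error")
  }
  if (!is_count(n_rounds, min = 1L)) {
    abort("`n_rounds` must be >= 1.",
          class = "morphocontrast_config_error")
  }
  n_batches <- ceiling(n_contrasts / batch_size)
  grp <- rep(seq_len(n_batches), each = batch_size)[seq_len(n_contrasts)]
  rounds <- with_seed(shuffle_seed, {
    lapply(seq_len(n_rounds), function(r) {
      ord <- sample.int(n_contrasts)
      unname(split(ord, grp))
    })
  })
  structure(rounds,
            class = "batch_plan",
            batch_size = as.integer(batch_size),
            n_contrasts = as.integer(n_contrasts),
            shuffle_seed = as.integer(shuffle_seed))
}

#' @export
print.batch_plan <- function(x, ...) {
  per_round <- length(x[[1]])
  total <- sum(lengths(x[[1]])) * length(x)
  cat(sprintf("<batch_plan> %d contrasts, batch %d: %d batches/round x %d rounds (%s presentations)\n",
              attr(x, "n_contrasts"), attr(x, "batch_size"), per_round,
              length(x), format(total, big.mark = ",")))
  invisible(x)
}
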