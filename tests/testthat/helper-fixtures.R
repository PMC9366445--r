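# Shared fixtures, all generated in code.

# Per-group sample sizes of the hairy-substrate study design (15 groups,
# 386 specimens total).
hairy_group_sizes <- c(34, 37, 32, 30, 32, 24, 22, 25, 21, 19, 21, 22, 20,
                       24, 23)

# A bare manifest (no pixels) with the given per-group sizes.
make_manifest <- function(per_group) {
  g <- length(per_group)
  tibble::tibble(
    specimen_id = unlist(lapply(seq_len(g), function(i) {
      sprintf("G%02d_s%03d", i, seq_len(per_group[i]))
    })),
    group = rep(sprintf("G%02d", seq_len(g)), per_group)
  )
}

# Small prepared synthetic set, memoised per (groups, per_group, delta, seed)
# so several test files can reuse the same fixture without regenerating.
.fixture_cache <- new.env(parent = emptyenv())
prepared_set <- function(n_groups, per_group, delta, seed,
                         image_size = 128) {
  key <- paste(n_groups, per_group, delta, seed, image_size, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    cfg <- synthetic_config(n_groups = n_groups, per_group = per_group,
                            delta = delta, seed = seed,
                            image_size = image_size)
    .fixture_cache[[key]] <- prep_images(generate_image_set(cfg))
  }
  .fixture_cache[[key]]
}

# Desk-scale training configuration used by fixtures (budget documented in
# the methods vignette).
desk_config <- function(n_rounds = 3, pairs_per_round = 512, seed = 1L) {
  train_config(n_rounds = n_rounds, pairs_per_round = pairs_per_round,
               learning_rate = 3e-3, init_seed = seed,
               shuffle_seed = seed + 50L)
}

# Random unit-range image matrix.
random_image <- function(n, seed) {
  withr::with_seed(seed, matrix(runif(n * n), n, n))
}
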