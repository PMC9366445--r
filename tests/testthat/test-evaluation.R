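test_that("confusion matrices conserve counts and expose accuracy", {
  truth <- rep(c("a", "b", "c"), c(4, 3, 5))
  pred <- truth
  pred[c(1, 8)] <- c("b", "a")
  cm <- confusion_matrix(truth, pred)
  expect_equal(rowSums(cm), c(a = 4, b = 3, c = 5))
  expect_equal(sum(cm), 12)
  expect_equal(accuracy(cm), sum(pred == truth) / 12)
  expect_error(confusion_matrix(character(), character()),
               class = "morphocontrast_config_error")
})

test_that("MCC is 1 on perfect tables, 0 on degenerate marginals", {
  for (sizes in list(c(3, 3), c(5, 1, 7), rep(4, 15))) {
    cm <- diag(sizes)
    expect_equal(mcc(cm), 1)
  }
  one_col <- cbind(c(4, 6), c(0, 0))
  expect_warning(v <- mcc(one_col), "degenerate")
  expect_equal(v, 0)
  # MCC = 1 iff all off-diagonal counts vanish
  off <- diag(c(4, 4, 4)); off[1, 2] <- 1
  expect_lt(mcc(off), 1)
})

test_that("multiclass MCC reduces to the binary formula on 2x2 tables", {
  expect_equal(mcc(rbind(c(2, 1), c(0, 3))), 1 / sqrt(2), tolerance = 1e-12)
  binary_mcc <- function(tp, fn, fp, tn) {
    (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  }
  withr::with_seed(17, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 5) + 1, 2, 2)
      expect_equal(mcc(tab),
                   binary_mcc(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                   tolerance = 1e-12)
    }
  })
})

test_that("MCC is invariant under simultaneous class relabelling", {
  withr::with_seed(18, {
    tab <- matrix(rpois(25, 3), 5, 5) + diag(5)
    base <- mcc(tab)
    for (i in 1:20) {
      pm <- sample(5)
      expect_equal(mcc(tab[pm, pm]), base, tolerance = 1e-12)
    }
  })
})

test_that("post-hoc identification is perfect on separable data, chance on noise", {
  pr <- prepared_set(n_groups = 3, per_group = 6, delta = 2, seed = 30)
  m <- train_contrast_cnn(pr, desk_config(n_rounds = 3, pairs_per_round = 512))
  ph <- post_hoc_identify(m, pr)
  expect_equal(ph$accuracy, 1)
  expect_equal(ph$mcc, 1)
  expect_equal(rowSums(ph$confusion), setNames(rep(6, 3), sort(unique(pr$group))))

  # untrained random weights on exchangeable (delta = 0) data: accuracy must
  # sit inside the label-permutation null band
  pr0 <- prepared_set(n_groups = 5, per_group = 8, delta = 0, seed = 44,
                      image_size = 64)
  spec <- network_spec()
  stub <- structure(list(weights = init_weights(spec, 5), spec = spec,
                         group_levels = sort(unique(pr0$group))),
                    class = "contrast_cnn")
  fs <- embed_set(stub, pr0)
  stub$centroids <- attr(fs, "centroids")
  obs <- post_hoc_identify(stub, pr0)$accuracy
  null_acc <- withr::with_seed(45, vapply(1:200, function(i) {
    perm <- pr0
    perm$group <- sample(perm$group)
    fsp <- embed_set(stub, perm)
    cls <- classify_nearest_centroid(fsp, group_centroids(fsp))
    mean(cls$assigned == perm$group)
  }, numeric(1)))
  expect_lte(obs, quantile(null_acc, 0.995))
  expect_gte(obs, quantile(null_acc, 0.005))

  expect_error(post_hoc_identify(m, pr[pr$group == "G01", ]),
               class = "morphocontrast_model_error")
})

test_that("the jackknife sequesters, retrains and aggregates correctly", {
  pr <- prepared_set(n_groups = 3, per_group = 6, delta = 2, seed = 30)
  cfg <- desk_config(n_rounds = 2, pairs_per_round = 256)
  jk <- jackknife(pr, n_holdout = 3, config = cfg, seed = 21)
  expect_length(jk$holdout_ids, 3)
  expect_true(all(jk$assignments$group_trained))
  # row sums of the aggregate confusion equal per-group holdout counts
  expect_equal(rowSums(jk$confusion),
               table(factor(jk$assignments$truth,
                            levels = sort(unique(pr$group)))) |> as.numeric() |>
                 setNames(sort(unique(pr$group))))
  # determinism: same seed, same report
  jk2 <- jackknife(pr, n_holdout = 3, config = cfg, seed = 21)
  expect_identical(jk$holdout_ids, jk2$holdout_ids)
  expect_identical(jk$assignments, jk2$assignments)

  empty <- jackknife(pr, n_holdout = 0, config = cfg, seed = 1)
  expect_length(empty$holdout_ids, 0)
  expect_true(is.na(empty$mcc))

  expect_error(jackknife(pr, n_holdout = nrow(pr), config = cfg),
               class = "morphocontrast_config_error")
})

test_that("a holdout that empties its group is flagged, not trained", {
  pr <- prepared_set(n_groups = 3, per_group = 6, delta = 2, seed = 30)
  solo <- dplyr::bind_rows(pr, dplyr::mutate(pr[1, ],
                                             specimen_id = "G99_s001",
                                             group = "G99"))
  # find a seed whose single holdout is the singleton specimen
  seed <- NULL
  for (s in 1:200) {
    ids <- morphocontrast:::with_seed(
      morphocontrast:::substream_seed(s, 1L),
      sample(solo$specimen_id, 1)
    )
    if (ids == "G99_s001") { seed <- s; break }
  }
  expect_false(is.null(seed))
  jk <- jackknife(solo, n_holdout = 1, config = desk_config(), seed = seed)
  expect_false(jk$assignments$group_trained[1])
  expect_true(is.na(jk$assignments$assigned[1]))
  expect_true(is.na(jk$mcc))
})
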