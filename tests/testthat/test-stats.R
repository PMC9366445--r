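test_that("scatter-matrix statistics match hand-computed toy values", {
  # 1-D, groups {0,1} and {2,3}: H = 4, E = 1 -> lambda 0.2, V 0.8
  sc <- matrix(c(0, 1, 2, 3), 4, 1)
  mv <- manova_stats(sc, c("a", "a", "b", "b"))
  expect_equal(mv$lambda_wilks, 0.2, tolerance = 1e-12)
  expect_equal(mv$pillai_V, 0.8, tolerance = 1e-12)

  # all groups carrying identical samples: H = 0 -> lambda 1, V 0
  same <- rbind(c(0, 1), c(2, 0), c(1, 1))
  X <- rbind(same, same, same)
  mv0 <- manova_stats(X, rep(c("a", "b", "c"), each = 3))
  expect_equal(mv0$lambda_wilks, 1, tolerance = 1e-12)
  expect_equal(mv0$pillai_V, 0, tolerance = 1e-12)
})

test_that("lambda and V equal the eigenvalue oracle on random instances", {
  withr::with_seed(50, {
    for (i in 1:10) {
      g <- sample(3:6, 1); p <- sample(2:4, 1)
      n_per <- sample(5:9, g, replace = TRUE)
      X <- matrix(rnorm(sum(n_per) * p), ncol = p) +
        matrix(rep(rnorm(g * p), rep(n_per, p)), ncol = p)
      gf <- rep(letters[1:g], n_per)
      mv <- manova_stats(X, gf)
      # independent route: eigenvalues of solve(E) %*% H
      sc <- morphocontrast:::scatter_matrices(X, gf)
      th <- Re(eigen(solve(sc$E) %*% sc$H, only.values = TRUE)$values)
      expect_equal(mv$lambda_wilks, prod(1 / (1 + th)), tolerance = 1e-10)
      expect_equal(mv$pillai_V, sum(th / (1 + th)), tolerance = 1e-10)
    }
  })
})

test_that("F approximations agree with stats::manova as cross-check", {
  withr::with_seed(51, {
    X <- matrix(rnorm(60 * 2), 60, 2) +
      matrix(rep(rnorm(4 * 2, sd = 1.5), rep(rep(15, 4), 2)), ncol = 2)
    gf <- factor(rep(letters[1:4], each = 15))
  })
  mv <- manova_stats(X, as.character(gf))
  fit <- stats::manova(X ~ gf)
  sw <- summary(fit, test = "Wilks")$stats
  sp <- summary(fit, test = "Pillai")$stats
  expect_equal(mv$lambda_wilks, unname(sw[1, "Wilks"]), tolerance = 1e-8)
  expect_equal(mv$F_wilks, unname(sw[1, "approx F"]), tolerance = 1e-8)
  expect_equal(unname(mv$df_wilks), unname(sw[1, c("num Df", "den Df")]),
               tolerance = 1e-8)
  expect_equal(mv$pillai_V, unname(sp[1, "Pillai"]), tolerance = 1e-8)
  expect_equal(mv$F_pillai, unname(sp[1, "approx F"]), tolerance = 1e-8)
  expect_equal(unname(mv$df_pillai), unname(sp[1, c("num Df", "den Df")]),
               tolerance = 1e-8)
})

test_that("degrees of freedom follow the p = 2 identities", {
  withr::with_seed(52, {
    for (g in c(5, 15)) {
      n_per <- sample(10:20, g, replace = TRUE)
      X <- matrix(rnorm(sum(n_per) * 2), ncol = 2)
      mv <- manova_stats(X, rep(sprintf("g%02d", 1:g), n_per))
      N <- sum(n_per)
      expect_equal(unname(mv$df_wilks), c(2 * (g - 1), 2 * (N - g - 1)))
      expect_equal(unname(mv$df_pillai[1]), 2 * (g - 1))
    }
  })
})

test_that("a singular within-group scatter warns or errors as requested", {
  X <- rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3), c(4, 4), c(5, 5))
  gf <- rep(c("a", "b"), each = 3)
  expect_warning(manova_stats(X, gf), "singular")
  expect_error(manova_stats(X, gf, fallback = FALSE),
               class = "morphocontrast_singularity_error")
})

test_that("permutation p-values behave at the extremes and under rotation", {
  # perfectly separated tight clusters: observed statistic strictly extreme
  withr::with_seed(60, {
    X <- rbind(matrix(rnorm(20, 0, 1e-3), 10, 2),
               matrix(rnorm(20, 10, 1e-3), 10, 2))
  })
  gf <- rep(c("a", "b"), each = 10)
  pt <- permutation_test(X, gf, n_perm = 99, seed = 3)
  expect_equal(pt$p_value, rep(1 / 100, 2))

  # n_perm = 1 admits only 0.5 or 1 under the add-one estimator
  p1 <- permutation_test(X, gf, n_perm = 1, seed = 4)
  expect_true(all(p1$p_value %in% c(0.5, 1)))

  # affine equivariance: rotation + translation leaves p-values unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  Xr <- sweep(X %*% R, 2, c(3, -2), `+`)
  ptr <- permutation_test(Xr, gf, n_perm = 99, seed = 3)
  expect_equal(ptr$p_value, pt$p_value, tolerance = 1e-12)
  expect_equal(ptr$observed, pt$observed, tolerance = 1e-9)

  # exchangeable labels: no significance under a fixed seed
  withr::with_seed(61, {
    X0 <- matrix(rnorm(80), 40, 2)
    g0 <- sample(rep(letters[1:4], 10))
  })
  p0 <- permutation_test(X0, g0, n_perm = 199, seed = 5)
  expect_true(all(p0$p_value > 0.05))
})

test_that("the within-group bootstrap brackets the observed statistics", {
  withr::with_seed(62, {
    X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
  })
  gf <- rep(c("a", "b"), each = 20)
  bt <- permutation_test(X, gf, n_perm = 200, seed = 6, method = "bootstrap")
  expect_true(all(c("lower", "upper") %in% names(bt)))
  expect_true(all(bt$lower <= bt$upper))
  expect_true(bt$observed[2] >= bt$lower[2] && bt$observed[2] <= bt$upper[2])
})

test_that("t-SNE ordination is seeded, validated and grid-shaped", {
  withr::with_seed(70, X <- matrix(rnorm(60 * 5), 60, 5))
  a <- tsne_ordination(X, perplexity = 5, iterations = c(100, 250), seed = 8)
  b <- tsne_ordination(X, perplexity = 5, iterations = c(100, 250), seed = 8)
  expect_equal(a, b)
  expect_equal(nrow(a), 2 * 60)
  expect_true(all(c("perplexity", "iterations", "dim_1", "dim_2") %in% names(a)))

  expect_error(tsne_ordination(X, perplexity = 60),
               class = "morphocontrast_config_error")
  expect_warning(tsne_ordination(X, perplexity = 25, iterations = 20),
                 "perplexity")

  # separated clusters stay separated in the ordination
  withr::with_seed(71, {
    Xc <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
                matrix(rnorm(60, 8, 0.1), 30, 2))
  })
  ord <- tsne_ordination(Xc, perplexity = 8, iterations = 1000, seed = 9)
  Y <- as.matrix(ord[, c("dim_1", "dim_2")])
  c1 <- colMeans(Y[1:30, ]); c2 <- colMeans(Y[31:60, ])
  gap <- sqrt(sum((c1 - c2)^2))
  spread <- sqrt(mean(rbind(sweep(Y[1:30, ], 2, c1),
                            sweep(Y[31:60, ], 2, c2))^2))
  expect_gt(gap, 3 * spread)
})

test_that("untrained delta = 0 images show no group structure in t-SNE space", {
  hits <- 0
  for (s in 1:10) {
    imgs <- generate_image_set(synthetic_config(n_groups = 4, per_group = 8,
                                                delta = 0, seed = 300 + s,
                                                image_size = 64))
    pr <- prep_images(imgs)
    ord <- tsne_ordination(pr, perplexity = 6, iterations = 250,
                           seed = 400 + s)
    pv <- permutation_test(as.matrix(ord[, c("dim_1", "dim_2")]),
                           ord$group, n_perm = 99, seed = 500 + s)
    if (all(pv$p_value > 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
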