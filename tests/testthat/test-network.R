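test_that("the default layer algebra matches the declared architecture", {
  spec <- network_spec()
  sh <- layer_shapes(spec)
  expect_equal(sh$conv1, c(10, 25, 25))
  expect_equal(sh$pool1, c(10, 12, 12))
  expect_equal(sh$conv2, c(20, 9, 9))
  expect_equal(sh$pool2, c(20, 4, 4))
  expect_equal(sh$flatten, 320)
  expect_equal(sh$output, 2)

  # parameter count by programmatic weight enumeration
  w <- init_weights(spec, 1)
  expect_equal(sum(vapply(w, length, 1L)), 4032L)
  expect_equal(n_params(spec), 4032L)

  # a 15-dimensional output head is the same network with a wider linear map
  spec15 <- network_spec(embed_dim = 15)
  expect_equal(sum(vapply(init_weights(spec15, 1), length, 1L)),
               n_params(spec15))
  expect_error(network_spec(input_size = 6),
               class = "morphocontrast_config_error")
})

test_that("forward pass honours the spec and collapses with zero weights", {
  spec <- network_spec()
  w <- init_weights(spec, 2)
  img <- random_image(28, 5)
  e <- nn_forward(w, spec, img, trace = TRUE)
  expect_length(e, 2)
  expect_equal(attr(e, "layer_shapes")$flatten, 320)

  w0 <- lapply(w, function(x) x * 0)
  expect_equal(unname(nn_forward(w0, spec, img)), c(0, 0))

  expect_error(nn_forward(w, spec, matrix(0.5, 10, 10)),
               class = "morphocontrast_model_error")
})

test_that("convolution equals a nested-loop cross-correlation oracle", {
  in_size <- 6; k <- 3
  img <- random_image(in_size, 7)
  kern <- matrix(rnorm(k * k), k, k)
  idx <- morphocontrast:::conv_indices(in_size, k)
  patches <- matrix(as.numeric(img)[idx], nrow(idx), ncol(idx))
  out <- matrix(patches %*% as.numeric(kern),
                in_size - k + 1, in_size - k + 1)
  oracle <- matrix(0, 4, 4)
  for (r in 1:4) for (c in 1:4) {
    s <- 0
    for (dr in 0:2) for (dc in 0:2) s <- s + img[r + dr, c + dc] * kern[dr + 1, dc + 1]
    oracle[r, c] <- s
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("contrastive loss takes its closed-form values", {
  expect_equal(contrastive_loss(c(1, 2), c(1, 2), TRUE), 0)
  expect_equal(contrastive_loss(c(0, 0), c(1.5, 0), FALSE, margin = 1), 0)
  expect_equal(contrastive_loss(c(0, 0), c(0.4, 0), FALSE, margin = 1), 0.36)
  expect_equal(contrastive_loss(c(0, 0), c(0.3, 0.4), TRUE), 0.25)
  expect_error(contrastive_loss(c(0, 0), c(0, 0, 0), TRUE),
               class = "morphocontrast_dimension_error")
})

test_that("analytic gradients match central differences through a toy spec", {
  spec <- network_spec(input_size = 12, kernel = 3, conv1_filters = 3,
                       conv2_filters = 4, embed_dim = 2)
  w <- init_weights(spec, 3)
  B <- 4
  X <- withr::with_seed(11, matrix(runif(2 * B * 144), 2 * B, 144))
  same <- c(TRUE, FALSE, FALSE, TRUE)
  loss_fn <- function(w) {
    emb <- morphocontrast:::nn_forward_batch(w, spec, X)$emb
    mean(contrastive_loss(emb[1:B, ], emb[B + 1:B, ], same))
  }
  fwd <- morphocontrast:::nn_forward_batch(w, spec, X, keep_cache = TRUE)
  g <- morphocontrast:::contrastive_loss_grad(fwd$emb[1:B, ],
                                              fwd$emb[B + 1:B, ], same)
  grads <- morphocontrast:::nn_backward_batch(w, spec, fwd$cache,
                                              rbind(g$dA, g$dB) / B)
  eps <- 1e-6
  for (nm in names(w)) {
    probe <- withr::with_seed(20, sample(length(w[[nm]]),
                                         min(12, length(w[[nm]]))))
    for (i in probe) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss_fn(wp) - loss_fn(wm)) / (2 * eps)
      an <- grads[[nm]][i]
      if (abs(num) > 1e-10 || abs(an) > 1e-10) {
        expect_lt(abs(num - an) / max(abs(num), abs(an)), 1e-4)
      }
    }
  }
})

test_that("mean pooling is selectable and differentiable", {
  spec <- network_spec(input_size = 12, kernel = 3, conv1_filters = 2,
                       conv2_filters = 3, embed_dim = 2, pool = "mean")
  w <- init_weights(spec, 4)
  X <- withr::with_seed(12, matrix(runif(4 * 144), 4, 144))
  fwd <- morphocontrast:::nn_forward_batch(w, spec, X, keep_cache = TRUE)
  expect_equal(dim(fwd$emb), c(4, 2))
  dE <- matrix(1, 4, 2)
  grads <- morphocontrast:::nn_backward_batch(w, spec, fwd$cache, dE)
  eps <- 1e-6
  wp <- w; wp$W1[1] <- wp$W1[1] + eps
  wm <- w; wm$W1[1] <- wm$W1[1] - eps
  num <- (sum(morphocontrast:::nn_forward_batch(wp, spec, X)$emb) -
            sum(morphocontrast:::nn_forward_batch(wm, spec, X)$emb)) / (2 * eps)
  expect_equal(grads$W1[1], num, tolerance = 1e-4)
})
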