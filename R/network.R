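#' Specification of the group-contrast LeNet-5 variant
#'
#' Defines the layer structure of the small convolutional network used for
#' embedded group-contrast training.  The default reproduces the classic
#' layer algebra for 28x28 grayscale inputs: conv (10 filters, 4x4, valid)
#' -> ramp (rectifier) -> 2x2 max pool -> conv (20 filters, 4x4) -> ramp ->
#' 2x2 pool -> flatten (320) -> linear map to an `embed_dim`-dimensional
#' embedding (2 by default, 15 optional).
#'
#' @param input_size Input side length in pixels (default 28).
#' @param kernel Convolution kernel side (default 4; valid convolution,
#'   stride 1).
#' @param conv1_filters,conv2_filters Filter counts (defaults 10 and 20).
#' @param pool `"max"` (default) or `"mean"` 2x2 pooling, stride 2.
#' @param embed_dim Output embedding dimension (default 2).
#' @return Object of class `network_spec` carrying the derived layer shapes
#'   (`conv1_out`, `pool1_out`, `conv2_out`, `pool2_out`, `flatten`).
#' @examples
#' spec <- network_spec()
#' spec$flatten       # 320
#' n_params(spec)     # 4032
#' @export
network_spec <- function(input_size = 28, kernel = 4, conv1_filters = 10,
                         conv2_filters = 20, pool = c("max", "mean"),
                         embed_dim = 2) {
  pool <- match.arg(pool)
  for (v in c("input_size", "kernel", "conv1_filters", "conv2_filters",
              "embed_dim")) {
    if (!is_count(get(v), min = 1L)) {
      abort(sprintf("`%s` must be a positive count.", v),
            class = "morphocontrast_config_error")
    }
  }
  conv1_out <- input_size - kernel + 1
  pool1_out <- conv1_out %/% 2
  conv2_out <- pool1_out - kernel + 1
  pool2_out <- conv2_out %/% 2
  if (conv1_out < 2 || conv2_out < 2 || pool2_out < 1) {
    abort("network_spec: layer algebra collapses (input too small for kernel).",
          class = "morphocontrast_config_error")
  }
  structure(
    list(input_size = as.integer(input_size), kernel = as.integer(kernel),
         conv1_filters = as.integer(conv1_filters),
         conv2_filters = as.integer(conv2_filters),
         pool = pool, embed_dim = as.integer(embed_dim),
         conv1_out = as.integer(conv1_out), pool1_out = as.integer(pool1_out),
         conv2_out = as.integer(conv2_out), pool2_out = as.integer(pool2_out),
         flatten = as.integer(conv2_filters * pool2_out^2)),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>\n")
  cat(sprintf("  input   1x%dx%d\n", x$input_size, x$input_size))
  cat(sprintf("  conv1   %dx%dx%d (kernel %dx%d) + ramp\n", x$conv1_filters,
              x$conv1_out, x$conv1_out, x$kernel, x$kernel))
  cat(sprintf("  pool1   %dx%dx%d (%s 2x2)\n", x$conv1_filters, x$pool1_out,
              x$pool1_out, x$pool))
  cat(sprintf("  conv2   %dx%dx%d + ramp\n", x$conv2_filters, x$conv2_out,
              x$conv2_out))
  cat(sprintf("  pool2   %dx%dx%d\n", x$conv2_filters, x$pool2_out, x$pool2_out))
  cat(sprintf("  flatten %d -> linear -> %d\n", x$flatten, x$embed_dim))
  cat(sprintf("  trainable parameters: %d\n", n_params(x)))
  invisible(x)
}

#' Trainable parameter count of a network specification
#'
#' @param spec A [network_spec()].
#' @return Integer count (4,032 for the default 2-D embedding spec).
#' @export
n_params <- function(spec) {
  k2 <- spec$kernel^2
  spec$conv1_filters * (k2 + 1L) +
    spec$conv2_filters * (k2 * spec$conv1_filters + 1L) +
    spec$flatten * spec$embed_dim + spec$embed_dim
}

#' Layer output shapes of a network specification
#'
#' @param spec A [network_spec()].
#' @return Named list of integer shape vectors (channels, height, width) per
#'   layer, plus the flatten length and embedding dimension.
#' @export
layer_shapes <- function(spec) {
  list(input  = c(1L, spec$input_size, spec$input_size),
       conv1  = c(spec$conv1_filters, spec$conv1_out, spec$conv1_out),
       ramp1  = c(spec$conv1_filters, spec$conv1_out, spec$conv1_out),
       pool1  = c(spec$conv1_filters, spec$pool1_out, spec$pool1_out),
       conv2  = c(spec$conv2_filters, spec$conv2_out, spec$conv2_out),
       ramp2  = c(spec$conv2_filters, spec$conv2_out, spec$conv2_out),
       pool2  = c(spec$conv2_filters, spec$pool2_out, spec$pool2_out),
       flatten = spec$flatten,
       output = spec$embed_dim)
}

# im2col index table: row p (output position, column-major over the output
# grid), column j (kernel tap, column-major), value = index into the
# column-major flattened in_size x in_size input.
conv_indices <- function(in_size, k) {
  out <- in_size - k + 1L
  pr <- rep(seq_len(out), out)
  pc <- rep(seq_len(out), each = out)
  idx <- matrix(0L, out * out, k * k)
  for (dc in seq_len(k)) {
    for (dr in seq_len(k)) {
      idx[, dr + (dc - 1L) * k] <- (pr + dr - 1L) + (pc + dc - 2L) * in_size
    }
  }
  idx
}

# 2x2 stride-2 pooling taps: 4 index vectors into the flattened input grid,
# one per tap; windows are disjoint and any trailing odd row/column is
# dropped (floor semantics).
pool_indices <- function(in_size) {
  out <- in_size %/% 2L
  qr <- rep(seq_len(out), out)
  qc <- rep(seq_len(out), each = out)
  cbind((2L * qr - 1L) + (2L * qc - 2L) * in_size,
        (2L * qr) + (2L * qc - 2L) * in_size,
        (2L * qr - 1L) + (2L * qc - 1L) * in_size,
        (2L * qr) + (2L * qc - 1L) * in_size)
}

#' Seeded weight initialisation
#'
#' Uniform fan-in initialisation: each weight is drawn from
#' U(-1/sqrt(fan_in), 1/sqrt(fan_in)); biases start at zero.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return Named list of weight matrices/vectors (`W1`, `b1`, `W2`, `b2`,
#'   `W3`, `b3`).
#' @export
init_weights <- function(spec, seed = 1L) {
  k2 <- spec$kernel^2
  with_seed(seed, {
    f1 <- k2
    f2 <- k2 * spec$conv1_filters
    f3 <- spec$flatten
    list(
      W1 = matrix(runif(k2 * spec$conv1_filters, -1, 1) / sqrt(f1),
                  k2, spec$conv1_filters),
      b1 = numeric(spec$conv1_filters),
      W2 = matrix(runif(f2 * spec$conv2_filters, -1, 1) / sqrt(f2),
                  f2, spec$conv2_filters),
      b2 = numeric(spec$conv2_filters),
      W3 = matrix(runif(f3 * spec$embed_dim, -1, 1) / sqrt(f3),
                  f3, spec$embed_dim),
      b3 = numeric(spec$embed_dim)
    )
  })
}

# Gather an im2col patch matrix for a batch.
# X: B x in_size^2 (rows = images); returns (B*P) x K in batch-fastest
# layout: row b + (p-1)*B holds the patch at output position p of image b.
# Batch-fastest layout lets the column-major reshape stand in for an
# explicit (and costly) aperm.
im2col_batch <- function(X, idx) {
  B <- nrow(X)
  tmp <- X[, as.vector(idx), drop = FALSE]          # B x (P*K)
  dim(tmp) <- c(B * nrow(idx), ncol(idx))
  tmp
}

# Row indices of output position set `pos` for every image, batch-fastest.
batch_rows <- function(pos, B) {
  rep((pos - 1L) * B, each = B) + seq_len(B)
}

add_bias <- function(Z, b) {
  Z + rep(b, each = nrow(Z))
}

# Batched forward pass.  X is B x input_size^2 (column-major flattened
# images, unit scale).  Returns embeddings (B x embed_dim) and, if
# keep_cache, the intermediates required for backpropagation.  All
# intermediate activations use the batch-fastest row layout of
# im2col_batch().
nn_forward_batch <- function(weights, spec, X, keep_cache = FALSE) {
  B <- nrow(X)
  c1 <- spec$conv1_out^2
  p1 <- spec$pool1_out^2
  c2 <- spec$conv2_out^2
  p2 <- spec$pool2_out^2
  f1 <- spec$conv1_filters
  f2 <- spec$conv2_filters
  k2 <- spec$kernel^2

  idx1 <- conv_indices(spec$input_size, spec$kernel)
  P1 <- im2col_batch(X, idx1)                              # (B*c1) x k2
  Z1 <- add_bias(P1 %*% weights$W1, weights$b1)            # (B*c1) x f1
  A1 <- Z1 * (Z1 > 0)

  pool1 <- pool_indices(spec$conv1_out)                    # p1 x 4
  rows1 <- lapply(1:4, function(t) batch_rows(pool1[, t], B))
  if (spec$pool == "max") {
    Y1 <- A1[rows1[[1L]], , drop = FALSE]
    amax1 <- matrix(1L, nrow(Y1), f1)
    for (t in 2:4) {
      cand <- A1[rows1[[t]], , drop = FALSE]
      sel <- cand > Y1
      amax1[sel] <- t
      Y1[sel] <- cand[sel]
    }
  } else {
    Y1 <- (A1[rows1[[1L]], , drop = FALSE] + A1[rows1[[2L]], , drop = FALSE] +
             A1[rows1[[3L]], , drop = FALSE] + A1[rows1[[4L]], , drop = FALSE]) / 4
    amax1 <- NULL
  }

  idx2 <- conv_indices(spec$pool1_out, spec$kernel)        # c2 x k2
  rows_j <- lapply(seq_len(k2), function(j) batch_rows(idx2[, j], B))
  P2 <- matrix(0, B * c2, k2 * f1)
  for (j in seq_len(k2)) {
    P2[, (seq_len(f1) - 1L) * k2 + j] <- Y1[rows_j[[j]], , drop = FALSE]
  }
  Z2 <- add_bias(P2 %*% weights$W2, weights$b2)            # (B*c2) x f2
  A2 <- Z2 * (Z2 > 0)

  pool2 <- pool_indices(spec$conv2_out)                    # p2 x 4
  rows2 <- lapply(1:4, function(t) batch_rows(pool2[, t], B))
  if (spec$pool == "max") {
    Y2 <- A2[rows2[[1L]], , drop = FALSE]
    amax2 <- matrix(1L, nrow(Y2), f2)
    for (t in 2:4) {
      cand <- A2[rows2[[t]], , drop = FALSE]
      sel <- cand > Y2
      amax2[sel] <- t
      Y2[sel] <- cand[sel]
    }
  } else {
    Y2 <- (A2[rows2[[1L]], , drop = FALSE] + A2[rows2[[2L]], , drop = FALSE] +
             A2[rows2[[3L]], , drop = FALSE] + A2[rows2[[4L]], , drop = FALSE]) / 4
    amax2 <- NULL
  }

  # flatten: with batch-fastest rows, Fmat[b, q + (c-1)*p2] = Y2[b + (q-1)*B, c]
  Fmat <- Y2
  dim(Fmat) <- c(B, p2 * f2)                               # B x flatten
  E <- add_bias(Fmat %*% weights$W3, weights$b3)           # B x embed_dim

  if (!keep_cache) return(list(emb = E))
  list(emb = E,
       cache = list(P1 = P1, mask1 = Z1 > 0, rows1 = rows1, amax1 = amax1,
                    Y1 = Y1, rows_j = rows_j, P2 = P2,
                    mask2 = Z2 > 0, rows2 = rows2, amax2 = amax2,
                    Fmat = Fmat, B = B, c1 = c1, p1 = p1, c2 = c2, p2 = p2,
                    f1 = f1, f2 = f2, k2 = k2))
}

# Backpropagate dE (B x embed_dim) through the cached forward pass.
# Returns gradients with the same structure as the weights.
nn_backward_batch <- function(weights, spec, cache, dE) {
  B <- cache$B
  p2 <- cache$p2
  f2 <- cache$f2
  f1 <- cache$f1
  k2 <- cache$k2

  dW3 <- crossprod(cache$Fmat, dE)
  db3 <- colSums(dE)
  dF <- dE %*% t(weights$W3)                               # B x flatten

  # unflatten to dY2 (batch-fastest rows): row b + (q-1)*B, col c
  dY2 <- dF
  dim(dY2) <- c(B * p2, f2)

  dA2 <- matrix(0, B * cache$c2, f2)
  for (t in 1:4) {
    rows <- cache$rows2[[t]]
    if (spec$pool == "max") {
      sel <- cache$amax2 == t
      tmp <- dA2[rows, , drop = FALSE]
      tmp[sel] <- tmp[sel] + dY2[sel]
      dA2[rows, ] <- tmp
    } else {
      dA2[rows, ] <- dA2[rows, , drop = FALSE] + dY2 / 4
    }
  }
  dZ2 <- dA2 * cache$mask2
  dW2 <- crossprod(cache$P2, dZ2)
  db2 <- colSums(dZ2)
  dP2 <- dZ2 %*% t(weights$W2)                             # (B*c2) x (k2*f1)

  dY1 <- matrix(0, B * cache$p1, f1)
  for (j in seq_len(k2)) {
    rows <- cache$rows_j[[j]]
    dY1[rows, ] <- dY1[rows, , drop = FALSE] +
      dP2[, (seq_len(f1) - 1L) * k2 + j, drop = FALSE]
  }

  dA1 <- matrix(0, B * cache$c1, f1)
  for (t in 1:4) {
    rows <- cache$rows1[[t]]
    if (spec$pool == "max") {
      sel <- cache$amax1 == t
      tmp <- dA1[rows, , drop = FALSE]
      tmp[sel] <- tmp[sel] + dY1[sel]
      dA1[rows, ] <- tmp
    } else {
      dA1[rows, ] <- dA1[rows, , drop = FALSE] + dY1 / 4
    }
  }
  dZ1 <- dA1 * cache$mask1
  dW1 <- crossprod(cache$P1, dZ1)
  db1 <- colSums(dZ1)

  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Forward pass: map images to embedding vectors
#'
#' @param weights Weight list from [init_weights()] or a trained model's
#'   `$weights`.
#' @param spec The matching [network_spec()].
#' @param images A single `input_size` x `input_size` matrix in \[0, 1\], a
#'   list of such matrices, or a manifest tibble with a `pixels` list-column.
#' @param trace Attach the declared layer shapes as an attribute (debug aid)?
#' @return One embedding vector, or an n x `embed_dim` matrix for multiple
#'   images.
#' @export
nn_forward <- function(weights, spec, images, trace = FALSE) {
  single <- is.matrix(images)
  if (single) images <- list(images)
  if (is.data.frame(images)) {
    X <- image_matrix(images)
  } else {
    ok <- vapply(images, function(m) {
      is.matrix(m) && all(dim(m) == spec$input_size)
    }, logical(1))
    if (!all(ok)) {
      abort("image size does not match the network specification.",
            class = "morphocontrast_model_error")
    }
    X <- t(vapply(images, function(m) as.numeric(to_unit_range(m)),
                  numeric(spec$input_size^2)))
  }
  if (ncol(X) != spec$input_size^2) {
    abort("image size does not match the network specification.",
          class = "morphocontrast_model_error")
  }
  E <- nn_forward_batch(weights, spec, X)$emb
  out <- if (single) drop(E) else E
  if (trace) attr(out, "layer_shapes") <- layer_shapes(spec)
  out
}
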