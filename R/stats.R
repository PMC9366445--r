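#' One-way MANOVA statistics on feature-space scores
#'
#' Computes Wilks' lambda and Pillai's trace from the between-group (H) and
#' within-group (E) scatter matrices of an n x p score matrix --
#' `lambda = det(E) / det(E + H)` and `V = trace(H (H + E)^-1)` -- together
#' with their parametric F approximations (Rao's approximation for lambda;
#' the standard Pillai F with `df1 = s(2m+s+1)`, `df2 = s(2n+s+1)` where
#' `s = min(p, g-1)`, `m = (|p-g+1|-1)/2` and `n = (N-g-p-1)/2`).  Strong
#' group separation drives lambda toward 0 and V toward its upper bound
#' `min(p, g-1)`.
#'
#' @param scores n x p numeric matrix, or a data frame / `feature_space`
#'   with `score_*` columns.
#' @param groups Group labels, length n (taken from a `group` column when
#'   `scores` is a data frame).
#' @param fallback Use a pseudo-inverse (with a warning) when the
#'   within-group scatter is singular?  Default `TRUE`; with `FALSE` a
#'   singularity error is raised.
#' @return Object of class `manova_result` with elements `lambda_wilks`,
#'   `pillai_V`, `F_wilks`, `F_pillai`, `df_wilks`, `df_pillai`, the MANOVA
#'   auxiliaries `s`, `m`, `n_aux`, and the problem size (`n`, `p`, `g`).
#' @examples
#' sc <- rbind(c(0), c(1), c(2), c(3))
#' manova_stats(sc, c("a", "a", "b", "b"))$lambda_wilks  # 0.2
#' @export
manova_stats <- function(scores, groups = NULL, fallback = TRUE) {
  xs <- scores_matrix(scores, groups)
  X <- xs$X
  gf <- xs$groups
  n <- nrow(X)
  p <- ncol(X)
  g <- length(unique(gf))
  if (g < 2L || n <= g) {
    abort("MANOVA requires n > g >= 2.",
          class = "morphocontrast_config_error")
  }
  sc <- scatter_matrices(X, gf)
  H <- sc$H
  E <- sc$E
  T_mat <- H + E
  if (rcond_safe(E) < .Machine$double.eps * 100) {
    if (!fallback) {
      abort("within-group scatter matrix is singular.",
            class = "morphocontrast_singularity_error")
    }
    warn("within-group scatter is singular; using a pseudo-inverse ridge.")
    E <- E + diag(1e-12 * max(diag(T_mat)) + 1e-300, p)
    T_mat <- H + E
  }
  lambda <- det(E) / det(T_mat)
  V <- sum(diag(H %*% solve(T_mat)))

  q <- g - 1
  s <- min(p, q)
  m <- (abs(p - g + 1) - 1) / 2
  n_aux <- (n - g - p - 1) / 2

  t_rao <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- n - 1 - (p + q + 1) / 2
  df1_w <- p * q
  df2_w <- w * t_rao - (p * q - 2) / 2
  lam_t <- lambda^(1 / t_rao)
  F_wilks <- if (lam_t > 0) (1 - lam_t) / lam_t * df2_w / df1_w else Inf

  df1_p <- s * (2 * m + s + 1)
  df2_p <- s * (2 * n_aux + s + 1)
  F_pillai <- if (V < s) (df2_p / df1_p) * V / (s - V) else Inf

  structure(
    list(lambda_wilks = lambda, pillai_V = V,
         F_wilks = F_wilks, F_pillai = F_pillai,
         df_wilks = c(df1 = df1_w, df2 = df2_w),
         df_pillai = c(df1 = df1_p, df2 = df2_p),
         s = s, m = m, n_aux = n_aux, n = n, p = p, g = g),
    class = "manova_result"
  )
}

scores_matrix <- function(scores, groups) {
  if (is.data.frame(scores)) {
    score_cols <- grep("^score_", names(scores), value = TRUE)
    if (length(score_cols) == 0L) {
      score_cols <- names(scores)[vapply(scores, is.numeric, TRUE)]
    }
    groups <- groups %||% scores[["group"]]
    X <- as.matrix(as_tibble(scores)[, score_cols])
  } else {
    X <- as.matrix(scores)
  }
  if (is.null(groups)) {
    abort("`groups` must be supplied.", class = "morphocontrast_config_error")
  }
  list(X = X, groups = as.character(groups))
}

scatter_matrices <- function(X, gf) {
  grand <- colMeans(X)
  Xc <- sweep(X, 2L, grand)
  T_mat <- crossprod(Xc)
  counts <- as.vector(table(gf)[sort(unique(gf))])
  gm <- rowsum(X, gf) / counts
  gmc <- sweep(gm, 2L, grand)
  H <- crossprod(gmc * sqrt(counts))
  list(H = H, E = T_mat - H, T_mat = T_mat)
}

rcond_safe <- function(m) {
  if (any(!is.finite(m))) return(0)
  tryCatch(rcond(m), error = function(e) 0)
}

# Fast lambda/V used inside resampling loops.
wilks_pillai <- function(X, gf) {
  sc <- scatter_matrices(X, gf)
  T_mat <- sc$T_mat
  lam <- det(sc$E) / det(T_mat)
  V <- sum(diag(sc$H %*% solve(T_mat)))
  c(lambda = lam, pillai = V)
}

#' @export
print.manova_result <- function(x, ...) {
  cat("<manova_result>\n")
  cat(sprintf("  n = %d, p = %d, g = %d (s = %d, m = %.1f, n_aux = %.1f)\n",
              x$n, x$p, x$g, x$s, x$m, x$n_aux))
  cat(sprintf("  Wilks' lambda = %.4g, F = %.4g, dof: %g, %g\n",
              x$lambda_wilks, x$F_wilks, x$df_wilks[1], x$df_wilks[2]))
  cat(sprintf("  Pillai trace  = %.4g, F = %.4g, dof: %g, %g\n",
              x$pillai_V, x$F_pillai, x$df_pillai[1], x$df_pillai[2]))
  invisible(x)
}

#' @method tidy manova_result
#' @export
tidy.manova_result <- function(x, ...) {
  tibble(statistic = c("wilks_lambda", "pillai_trace"),
         value = c(x$lambda_wilks, x$pillai_V),
         f_value = c(x$F_wilks, x$F_pillai),
         df1 = c(x$df_wilks[1], x$df_pillai[1]),
         df2 = c(x$df_wilks[2], x$df_pillai[2]))
}

#' @method glance manova_result
#' @export
glance.manova_result <- function(x, ...) {
  tibble(lambda_wilks = x$lambda_wilks, pillai_V = x$pillai_V,
         F_wilks = x$F_wilks, F_pillai = x$F_pillai, n = x$n, p = x$p,
         g = x$g)
}

#' Permutation (or within-group bootstrap) test of group separation
#'
#' Nonparametric significance of the feature-space group separation.  The
#' default permutation test reassigns group labels `n_perm` times and
#' estimates, with the add-one estimator `p = (1 + extreme) / (n_perm + 1)`,
#' how often a permuted statistic is at least as extreme as the observed one
#' (smaller for Wilks' lambda, larger for Pillai's trace).  The
#' `"bootstrap"` method instead resamples specimens within groups with
#' replacement and reports percentile confidence intervals of the two
#' statistics.
#'
#' @param scores,groups As in [manova_stats()].
#' @param n_perm Number of permutations / resamples (default 1000).
#' @param seed Integer seed.
#' @param method `"permutation"` (default) or `"bootstrap"`.
#' @param conf Confidence level for bootstrap intervals (default 0.95).
#' @return Tibble with one row per statistic: `statistic`, `observed`, and
#'   either `p_value` + `n_perm` (permutation) or `lower` + `upper`
#'   (bootstrap).
#' @export
permutation_test <- function(scores, groups = NULL, n_perm = 1000, seed = 1L,
                             method = c("permutation", "bootstrap"),
                             conf = 0.95) {
  method <- match.arg(method)
  if (!is_count(n_perm, 1L)) {
    abort("`n_perm` must be a positive count.",
          class = "morphocontrast_config_error")
  }
  xs <- scores_matrix(scores, groups)
  X <- xs$X
  gf <- xs$groups
  obs <- wilks_pillai(X, gf)
  if (method == "permutation") {
    res <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) wilks_pillai(X, sample(gf)),
             numeric(2))
    })
    p_lam <- (1 + sum(res["lambda", ] <= obs["lambda"])) / (n_perm + 1)
    p_pil <- (1 + sum(res["pillai", ] >= obs["pillai"])) / (n_perm + 1)
    tibble(statistic = c("wilks_lambda", "pillai_trace"),
           observed = unname(obs),
           p_value = c(p_lam, p_pil),
           n_perm = n_perm)
  } else {
    idx_by_group <- split(seq_along(gf), gf)
    res <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        take <- unlist(lapply(idx_by_group, function(ix) {
          sample(ix, length(ix), replace = TRUE)
        }), use.names = FALSE)
        wilks_pillai(X[take, , drop = FALSE], gf[take])
      }, numeric(2))
    })
    a <- (1 - conf) / 2
    tibble(statistic = c("wilks_lambda", "pillai_trace"),
           observed = unname(obs),
           lower = c(quantile(res["lambda", ], a, names = FALSE),
                     quantile(res["pillai", ], a, names = FALSE)),
           upper = c(quantile(res["lambda", ], 1 - a, names = FALSE),
                     quantile(res["pillai", ], 1 - a, names = FALSE)))
  }
}

#' t-SNE ordination over a perplexity and iteration grid
#'
#' Exact (non-approximated) t-distributed stochastic neighbor embedding of
#' either raw flattened images (the untrained image space) or trained
#' feature-space scores.  Because apparent clustering can be a t-SNE
#' artifact, the ordination is run over a grid of perplexity and iteration
#' settings; each grid cell is seed-reproducible.  Gradient descent uses the
#' standard schedule (early exaggeration, momentum switch, adaptive gains);
#' the iteration grid is produced by snapshotting one descent at the
#' requested iteration counts.
#'
#' @param x n x p matrix, `feature_space` tibble, or image-set tibble with a
#'   `pixels` list-column (flattened to pixel vectors).
#' @param perplexity Numeric vector of perplexities (default
#'   `c(5, 15, 30, 50)`); each must satisfy `perplexity < n`, and
#'   `n > 3 * perplexity` is recommended (warned otherwise).  Values
#'   incompatible with a small `n` raise a configuration error.
#' @param iterations Integer vector of iteration counts (default
#'   `c(250, 1000)`).
#' @param dims Output dimensionality, 2 or 3.
#' @param seed Integer seed.
#' @return Object of class `tsne_ordination`: a tibble with columns
#'   `perplexity`, `iterations`, `specimen_id`/`group` (when available) and
#'   `dim_1..dim_k`.
#' @export
tsne_ordination <- function(x, perplexity = c(5, 15, 30, 50),
                            iterations = c(250, 1000), dims = 2, seed = 1L) {
  if (!dims %in% c(2, 3)) {
    abort("`dims` must be 2 or 3.", class = "morphocontrast_config_error")
  }
  meta <- NULL
  if (is.data.frame(x)) {
    meta <- as_tibble(x)[, intersect(c("specimen_id", "group"), names(x))]
    X <- if ("pixels" %in% names(x)) image_matrix(x)
         else scores_matrix(x, groups = x[["group"]])$X
  } else {
    X <- as.matrix(x)
  }
  n <- nrow(X)
  if (any(perplexity >= n)) {
    abort("every `perplexity` must be smaller than the number of points.",
          class = "morphocontrast_config_error")
  }
  if (any(n <= 3 * perplexity)) {
    warn("n <= 3 * perplexity for some grid cells; ordination may be unstable.")
  }
  iterations <- sort(unique(as.integer(iterations)))
  out <- list()
  for (pp in perplexity) {
    snaps <- tsne_exact(X, perplexity = pp, max_iter = max(iterations),
                        snapshots = iterations, dims = dims,
                        seed = substream_seed(seed, round(pp * 1000)))
    for (it in as.character(iterations)) {
      Y <- snaps[[it]]
      colnames(Y) <- paste0("dim_", seq_len(dims))
      cell <- dplyr::bind_cols(
        tibble(perplexity = pp, iterations = as.integer(it)),
        if (!is.null(meta)) meta else tibble(.row = seq_len(n)),
        as_tibble(Y)
      )
      out[[length(out) + 1L]] <- cell
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("tsne_ordination", class(res))
  res
}

# Exact t-SNE with snapshots.  Returns a named list of n x dims matrices,
# one per requested snapshot iteration.
tsne_exact <- function(X, perplexity, max_iter, snapshots, dims = 2,
                       seed = 1L) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    beta_min <- -Inf
    beta_max <- Inf
    di <- D2[i, -i]
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) {
        H <- 0
      } else {
        pj <- w / sw
        H <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      }
      diff <- H - logU
      if (abs(diff) < 1e-6) break
      if (diff > 0) {           # entropy too high -> sharpen
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- w / max(sum(w), 1e-300)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  exaggeration <- 4
  stop_exag <- min(100L, max_iter)
  momentum <- 0.5
  eta <- 200
  Y <- with_seed(seed, matrix(rnorm(n * dims, sd = 1e-4), n, dims))
  inc <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  out <- list()
  for (it in seq_len(max_iter)) {
    Pe <- if (it <= stop_exag) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
    if (it == 250L) momentum <- 0.8
    if (it %in% snapshots) out[[as.character(it)]] <- Y
  }
  out
}
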