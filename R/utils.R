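#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile rnorm runif setNames
#' @importFrom utils head modifyList
NULL

# Run `code` under a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Independent substreams derived from one user-facing seed.  Keeps every
# derived seed a valid 32-bit integer so stages can be re-run separately.
substream_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + 7919 * as.numeric(stream)
  as.integer(s %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > min || (allow_zero && x == min))
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s.",
                  name, if (allow_zero) ">=" else ">", format(min)),
          class = "morphocontrast_config_error")
  }
  invisible(x)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

# FNV-1a hash of a deparsed object; used for provenance digests in run
# manifests (not for cryptography).
config_digest <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

as_pixel_matrix <- function(x, name = "img") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name),
          class = "morphocontrast_format_error")
  }
  if (anyNA(x)) {
    abort(sprintf("`%s` contains missing pixel values.", name),
          class = "morphocontrast_format_error")
  }
  x
}

# Images arrive either 8-bit [0, 255] or already unit-scaled [0, 1].
to_unit_range <- function(img) {
  if (max(img) > 1 + 1e-8) img / 255 else img
}
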