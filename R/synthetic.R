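#' Configuration for the synthetic puparium-image generator
#'
#' Builds and validates the parameter set for [generate_image_set()].  The
#' generator emulates the statistical structure of puparium photomicrograph
#' collections: `n_groups` morphological groups of `per_group` specimens each,
#' rendered as 8-bit grayscale images of an elongate superellipse outline with
#' a posterior interior blob (a vasiform-orifice analogue), transverse
#' segmentation bands and a crenulate margin, on a pure-white background.
#'
#' Group identity shifts the shape parameters by `delta` times a group-specific
#' unit-norm offset direction, so `delta` acts as a single interpretable
#' between-group effect size: `delta = 0` makes group labels carry no
#' information (images are group-exchangeable), while `delta >= 1` yields
#' clearly separable groups.  Specimen identity adds small jitter (rotation,
#' scale, brightness, pixel noise); the `substrate` factor applies one fixed
#' global shape perturbation to all groups, mimicking the effect of rearing on
#' hairy versus glabrous (smooth) host-plant leaves.
#'
#' @param n_groups Number of groups (>= 2).
#' @param per_group Specimens per group: a single count or a length-`n_groups`
#'   vector of counts (all >= 1).
#' @param delta Non-negative between-group effect size.
#' @param substrate `"hairy"` or `"glabrous"`; hairy rearing elongates the
#'   outline and amplifies the margin crenulation.
#' @param jitter Named list of within-group jitter standard deviations:
#'   `rotation_sd` (degrees), `scale_sd` (fraction), `brightness_sd`
#'   (gray-level units on \[0,1\]), `noise_sd` (additive pixel noise on
#'   \[0,1\], applied inside the specimen only).
#' @param image_size Canvas side in pixels (before preparation; >= 32).
#' @param seed Integer seed; the same seed and configuration reproduce a
#'   bit-identical image set.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_image_set()], [write_image_set()]
#' @export
synthetic_config <- function(n_groups = 15,
                             per_group = 25,
                             delta = 1,
                             substrate = c("hairy", "glabrous"),
                             jitter = list(rotation_sd = 3,
                                           scale_sd = 0.03,
                                           brightness_sd = 0.03,
                                           noise_sd = 0.01),
                             image_size = 128,
                             seed = 1L) {
  substrate <- match.arg(substrate)
  if (!is_count(n_groups, min = 2L)) {
    abort("`n_groups` must be an integer >= 2.",
          class = "morphocontrast_config_error")
  }
  n_groups <- as.integer(n_groups)
  if (length(per_group) == 1L) per_group <- rep(per_group, n_groups)
  if (length(per_group) != n_groups || !all(vapply(per_group, is_count, TRUE, min = 1L))) {
    abort("`per_group` must be one count or `n_groups` counts, all >= 1.",
          class = "morphocontrast_config_error")
  }
  per_group <- as.integer(per_group)
  stopifnot_scalar_number(delta, "delta", min = 0)
  default_jitter <- list(rotation_sd = 3, scale_sd = 0.03,
                         brightness_sd = 0.03, noise_sd = 0.01)
  jitter <- modifyList(default_jitter, as.list(jitter))
  for (nm in names(default_jitter)) {
    stopifnot_scalar_number(jitter[[nm]], paste0("jitter$", nm), min = 0)
  }
  if (!is_count(image_size, min = 32L)) {
    abort("`image_size` must be an integer >= 32.",
          class = "morphocontrast_config_error")
  }
  if (!is_count(abs(seed))) {
    abort("`seed` must be an integer.", class = "morphocontrast_config_error")
  }
  structure(
    list(n_groups = n_groups, per_group = per_group, delta = delta,
         substrate = substrate, jitter = jitter,
         image_size = as.integer(image_size), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  groups: %d  specimens: %d  delta: %g  substrate: %s\n",
              x$n_groups, sum(x$per_group), x$delta, x$substrate))
  cat(sprintf("  image: %dx%d px  seed: %d\n", x$image_size, x$image_size, x$seed))
  invisible(x)
}

# Baseline shape parameters of the rendered puparium analogue.  Units are
# relative to the half-canvas except where noted.
base_shape_params <- function(substrate) {
  p <- c(aspect   = 1.55,  # length / width of the outline
         exponent = 2.4,   # superellipse exponent (2 = ellipse)
         cren_amp = 0.012, # margin crenulation amplitude (fraction of radius)
         cren_freq = 24,   # crenulation lobes around the margin
         blob_u   = -0.50, # interior blob position along the body axis
         blob_sd  = 0.10)  # interior blob spread
  if (substrate == "hairy") {
    p[["aspect"]] <- p[["aspect"]] + 0.12
    p[["cren_amp"]] <- p[["cren_amp"]] + 0.004
  }
  p
}

# Per-dimension scales converting the unit-norm group offset direction into
# shape-parameter units; `delta` multiplies the whole vector.
shape_offset_scales <- function() {
  c(aspect = 0.10, exponent = 0.30, cren_amp = 0.006,
    cren_freq = 3.0, blob_u = 0.08, blob_sd = 0.015)
}

# Render one specimen image.  Deterministic given its arguments; all
# randomness lives in the caller's jitter/noise draws.
render_specimen <- function(size, params, rotation, scale, brightness, noise) {
  len <- 0.72 * scale
  ax <- seq_len(size)
  cc <- (ax - 0.5) / size * 2 - 1
  x <- matrix(cc, size, size, byrow = TRUE)   # column -> x
  y <- matrix(cc, size, size)                 # row -> y
  th <- rotation * pi / 180
  xr <- cos(th) * x + sin(th) * y
  yr <- -sin(th) * x + cos(th) * y
  u <- xr / len
  v <- yr / (len / params[["aspect"]])
  r <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  e <- params[["exponent"]]
  r_super <- (abs(cos(phi))^e + abs(sin(phi))^e)^(-1 / e)
  boundary <- r_super * (1 + params[["cren_amp"]] *
                           sin(params[["cren_freq"]] * phi))
  q <- r / boundary
  # soft edge about 1.5 px wide, in boundary-normalised units
  w <- 1.5 * (2 / size) / len
  alpha <- pmin(pmax((1 - q) / w, 0), 1)
  body <- 0.55 + brightness + 0.10 * q +
    0.05 * sin(9 * pi * u) -
    0.35 * exp(-((u - params[["blob_u"]])^2 + v^2) / (2 * params[["blob_sd"]]^2))
  img <- alpha * body + (1 - alpha)
  inside <- alpha > 0
  img[inside] <- img[inside] + noise[inside]
  img <- pmin(pmax(img, 0), 1)
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Generate a labelled synthetic specimen-image set
#'
#' Produces `sum(per_group)` 8-bit grayscale images according to a
#' [synthetic_config()], together with a manifest.  One global seed drives
#' three independent substreams (group shape offsets, specimen jitter,
#' pixel noise), so identical configurations reproduce bit-identical sets.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with one row per specimen and columns `specimen_id`,
#'   `group`, `substrate`, and `pixels` (a list-column of integer matrices
#'   with values in 0--255; background is pure white, 255).
#' @examples
#' imgs <- generate_image_set(synthetic_config(n_groups = 3, per_group = 4,
#'                                             delta = 1, seed = 1))
#' nrow(imgs)
#' @export
generate_image_set <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be created by synthetic_config().",
          class = "morphocontrast_config_error")
  }
  g <- config$n_groups
  scales <- shape_offset_scales()
  offsets <- with_seed(substream_seed(config$seed, 1L), {
    m <- matrix(rnorm(g * length(scales)), g, length(scales))
    m / sqrt(rowSums(m^2))  # unit-norm direction per group
  })
  base <- base_shape_params(config$substrate)
  group_labels <- sprintf("G%02d", seq_len(g))
  jt <- config$jitter
  sz <- config$image_size

  rows <- with_seed(substream_seed(config$seed, 2L), {
    out <- vector("list", sum(config$per_group))
    k <- 0L
    for (i in seq_len(g)) {
      params <- base
      shift <- config$delta * offsets[i, ] * scales
      for (nm in names(scales)) params[[nm]] <- params[[nm]] + shift[[nm]]
      params[["cren_amp"]] <- max(params[["cren_amp"]], 0)
      params[["blob_sd"]] <- max(params[["blob_sd"]], 0.02)
      params[["aspect"]] <- max(params[["aspect"]], 1.05)
      for (j in seq_len(config$per_group[i])) {
        k <- k + 1L
        rotation <- rnorm(1, 0, jt$rotation_sd)
        scale <- max(rnorm(1, 1, jt$scale_sd), 0.5)
        brightness <- rnorm(1, 0, jt$brightness_sd)
        noise <- matrix(rnorm(sz * sz, 0, jt$noise_sd), sz, sz)
        px <- render_specimen(sz, params, rotation, scale, brightness, noise)
        out[[k]] <- tibble(
          specimen_id = sprintf("%s_s%03d", group_labels[i], j),
          group = group_labels[i],
          substrate = config$substrate,
          pixels = list(px)
        )
      }
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "synthetic_config") <- config
  res
}

#' Write an image set to disk as PNG files plus a CSV manifest
#'
#' @param images Tibble from [generate_image_set()] or [prep_images()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble (columns `path`, `specimen_id`, `group`,
#'   `substrate`), invisibly also written to `manifest.csv` in `dir`.
#' @export
write_image_set <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(images$specimen_id, ".png"))
  purrr::walk2(images$pixels, paths, function(px, p) {
    png::writePNG(to_unit_range(px), p)
  })
  manifest <- tibble(path = paths,
                     specimen_id = images$specimen_id,
                     group = images$group,
                     substrate = images$substrate)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Read an image set from a CSV manifest
#'
#' @param manifest Path to a `manifest.csv` (columns `path,specimen_id,group,
#'   substrate`) or an equivalent data frame.  Relative `path` entries are
#'   resolved against the manifest's directory.
#' @return Tibble with the same columns plus a `pixels` list-column
#'   (8-bit integer matrices for grayscale files; HxWx3 arrays for RGB).
#' @export
read_image_set <- function(manifest) {
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  manifest <- as_tibble(manifest)
  if (anyDuplicated(manifest$specimen_id)) {
    abort("manifest contains duplicate specimen ids.",
          class = "morphocontrast_manifest_error")
  }
  manifest$pixels <- purrr::map(manifest$path, function(p) {
    if (!file.exists(p)) p <- file.path(base_dir, p)
    px <- png::readPNG(p)
    if (length(dim(px)) == 3 && dim(px)[3] >= 3) {
      px <- px[, , 1:3] * 255
    } else {
      if (length(dim(px)) == 3) px <- px[, , 1]
      px <- round(px * 255)
      storage.mode(px) <- "integer"
    }
    px
  })
  manifest
}
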