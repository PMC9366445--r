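#' Von Kries chromatic-adaptation grayscale conversion
#'
#' Converts an RGB image to grayscale via chromatic adaptation in
#' cone-response space: the sRGB values are linearised, mapped to XYZ and
#' then to LMS cone responses (Hunt-Pointer-Estevez matrix), rescaled by the
#' ratio of the D65 cone response to the adopted white point's cone response
#' (the Von Kries transform), converted back to XYZ, and the luminance
#' channel is gamma-encoded to give the grayscale value.  With the default
#' D65 white point the adaptation is the identity, so achromatic pixels
#' `(v, v, v)` map to `v/255`.
#'
#' @param rgb_image Height x width x 3 numeric array, values in \[0, 255\] or
#'   \[0, 1\].
#' @param white_point Adopted white of the scene: one of `"D65"`, `"D50"`,
#'   `"D55"`, `"A"`, `"E"`.
#' @return Height x width matrix with values in \[0, 1\].
#' @export
von_kries_grayscale <- function(rgb_image, white_point = "D65") {
  d <- dim(rgb_image)
  if (length(d) != 3L || d[3] != 3L) {
    abort("`rgb_image` must be a height x width x 3 array.",
          class = "morphocontrast_format_error")
  }
  whites <- list(  # XYZ tristimulus of the adopted whites (Y = 1)
    D65 = c(0.95047, 1.00000, 1.08883),
    D50 = c(0.96422, 1.00000, 0.82521),
    D55 = c(0.95682, 1.00000, 0.92149),
    A   = c(1.09850, 1.00000, 0.35585),
    E   = c(1.00000, 1.00000, 1.00000)
  )
  if (!white_point %in% names(whites)) {
    abort(sprintf("unknown white point \"%s\"; use one of %s.", white_point,
                  paste(names(whites), collapse = ", ")),
          class = "morphocontrast_config_error")
  }
  rgb <- rgb_image
  if (max(rgb) > 1 + 1e-8) rgb <- rgb / 255
  # sRGB decoding (IEC 61966-2-1)
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  m_rgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                        0.2126729, 0.7151522, 0.0721750,
                        0.0193339, 0.1191920, 0.9503041),
                      3, 3, byrow = TRUE)
  m_hpe <- matrix(c( 0.40024, 0.70760, -0.08081,   # XYZ -> LMS (HPE)
                    -0.22630, 1.16532,  0.04570,
                     0.00000, 0.00000,  0.91822),
                  3, 3, byrow = TRUE)
  n <- d[1] * d[2]
  rgb_flat <- matrix(lin, n, 3)
  xyz <- rgb_flat %*% t(m_rgb2xyz)
  lms <- xyz %*% t(m_hpe)
  lms_src <- as.numeric(m_hpe %*% whites[[white_point]])
  lms_dst <- as.numeric(m_hpe %*% whites[["D65"]])
  lms_adapted <- sweep(lms, 2, lms_dst / lms_src, `*`)
  xyz_adapted <- lms_adapted %*% t(solve(m_hpe))
  y <- pmin(pmax(xyz_adapted[, 2], 0), 1)
  # sRGB encoding of the luminance channel
  gray <- ifelse(y <= 0.0031308, y * 12.92, 1.055 * y^(1 / 2.4) - 0.055)
  matrix(pmin(pmax(gray, 0), 1), d[1], d[2])
}

#' Percentile exposure normalisation
#'
#' Automated surrogate for by-hand brightness/contrast editing: linearly
#' rescales so that the `low_pct` percentile maps to 0 and the `high_pct`
#' percentile maps to 1, clipping to \[0, 1\].
#'
#' @param img Numeric matrix, values in \[0, 1\].
#' @param low_pct,high_pct Percentile fractions, `low_pct < high_pct`.
#' @return Rescaled matrix.  A constant image is returned unchanged with a
#'   warning (no division by zero).
#' @export
normalize_exposure <- function(img, low_pct = 0.01, high_pct = 0.99) {
  img <- as_pixel_matrix(img)
  if (low_pct >= high_pct) {
    abort("`low_pct` must be smaller than `high_pct`.",
          class = "morphocontrast_config_error")
  }
  q <- quantile(img, c(low_pct, high_pct), names = FALSE)
  if (q[2] - q[1] <= .Machine$double.eps) {
    warn("constant image: exposure normalisation skipped.")
    return(img)
  }
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Crop to the specimen and centre it on a square pure-white frame
#'
#' Finds the tight bounding box of non-background pixels (darker than
#' `background_threshold`) and copies it, centred, onto a square white frame
#' whose side is the larger bounding-box dimension.
#'
#' @param img Numeric matrix in \[0, 1\], specimen dark on light background.
#' @param background_threshold Pixels with values `>= background_threshold`
#'   count as background (default 0.98 of full white).
#' @return Square matrix; frame pixels are exactly 1.
#' @export
crop_and_frame <- function(img, background_threshold = 0.98) {
  img <- as_pixel_matrix(img)
  fg <- img < background_threshold
  if (!any(fg)) {
    abort("image contains no specimen pixels below the background threshold.",
          class = "morphocontrast_empty_specimen_error")
  }
  rows <- range(which(rowSums(fg) > 0))
  cols <- range(which(colSums(fg) > 0))
  box <- img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  side <- max(dim(box))
  frame <- matrix(1, side, side)
  r0 <- (side - nrow(box)) %/% 2
  c0 <- (side - ncol(box)) %/% 2
  frame[r0 + seq_len(nrow(box)), c0 + seq_len(ncol(box))] <- box
  frame
}

# Row-aggregation matrix for exact area-average resampling from n source
# pixels to t target pixels; each row sums to 1 and every source pixel
# receives total weight t/n, so the image mean is preserved exactly.
area_weights <- function(n, t) {
  w <- matrix(0, t, n)
  step <- n / t
  for (i in seq_len(t)) {
    lo <- (i - 1) * step
    hi <- i * step
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:j1) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) w[i, j] <- overlap / step
    }
  }
  w
}

#' Step an image down to the network's input resolution
#'
#' Resamples to `target` x `target` pixels.  The default area-average kernel
#' computes each output pixel as the exact mean of its source area, which
#' preserves the image mean and maps constants to constants; bilinear
#' interpolation is available as an alternative.
#'
#' @param img Numeric matrix in \[0, 1\], at least `target` pixels per side.
#' @param target Output side length (default 28).
#' @param method `"area"` (default) or `"bilinear"`.
#' @return `target` x `target` matrix in \[0, 1\].
#' @export
step_down <- function(img, target = 28, method = c("area", "bilinear")) {
  img <- as_pixel_matrix(img)
  method <- match.arg(method)
  if (nrow(img) < target || ncol(img) < target) {
    abort(sprintf("step_down() only reduces resolution: source is %dx%d, target %d.",
                  nrow(img), ncol(img), target),
          class = "morphocontrast_config_error")
  }
  if (nrow(img) == target && ncol(img) == target) return(img)
  if (method == "area") {
    wr <- area_weights(nrow(img), target)
    wc <- area_weights(ncol(img), target)
    out <- wr %*% img %*% t(wc)
  } else {
    src_r <- (seq_len(target) - 0.5) * nrow(img) / target + 0.5
    src_c <- (seq_len(target) - 0.5) * ncol(img) / target + 0.5
    interp1 <- function(pos, n) {
      p <- pmin(pmax(pos, 1), n)
      i0 <- pmin(floor(p), n - 1)
      list(i0 = i0, f = p - i0)
    }
    r <- interp1(src_r, nrow(img)); cl <- interp1(src_c, ncol(img))
    out <- (1 - r$f) * ((1 - rep(cl$f, each = target)) * img[r$i0, cl$i0] +
                          rep(cl$f, each = target) * img[r$i0, cl$i0 + 1]) +
      r$f * ((1 - rep(cl$f, each = target)) * img[r$i0 + 1, cl$i0] +
               rep(cl$f, each = target) * img[r$i0 + 1, cl$i0 + 1])
  }
  pmin(pmax(out, 0), 1)
}

#' Prepare an image set for the contrast network
#'
#' Applies the fixed preparation chain -- grayscale conversion (RGB inputs
#' only), percentile exposure normalisation, white-frame cropping, and
#' area-average step-down -- to every image of a manifest tibble.  Images
#' that already match the target geometry (`target_size` x `target_size`,
#' values in \[0, 1\]) are passed through unchanged, which makes the chain
#' idempotent on prepared sets.
#'
#' @param images Tibble with a `pixels` list-column (from
#'   [generate_image_set()] or [read_image_set()]).
#' @param target_size Side length of prepared images (default 28).
#' @param low_pct,high_pct Percentiles for [normalize_exposure()].
#' @param background_threshold Passed to [crop_and_frame()].
#' @param white_point Passed to [von_kries_grayscale()] for RGB inputs.
#' @param method Resampling kernel for [step_down()].
#' @return The input tibble with `pixels` replaced by prepared
#'   `target_size` x `target_size` matrices in \[0, 1\]; preparation
#'   parameters are recorded in the `prep_params` attribute.
#' @export
prep_images <- function(images, target_size = 28, low_pct = 0.01,
                        high_pct = 0.99, background_threshold = 0.98,
                        white_point = "D65", method = "area") {
  images <- as_tibble(images)
  images$pixels <- purrr::map(images$pixels, function(px) {
    if (length(dim(px)) == 3L) px <- von_kries_grayscale(px, white_point)
    px <- to_unit_range(px)
    if (nrow(px) == target_size && ncol(px) == target_size &&
        min(px) >= 0 && max(px) <= 1) {
      return(px)  # already prepared
    }
    px <- normalize_exposure(px, low_pct, high_pct)
    px <- crop_and_frame(px, background_threshold)
    if (nrow(px) < target_size) {
      # small specimens are padded with white rather than upscaled
      pad <- matrix(1, target_size, target_size)
      off <- (target_size - nrow(px)) %/% 2
      pad[off + seq_len(nrow(px)), off + seq_len(ncol(px))] <- px
      px <- pad
    }
    step_down(px, target_size, method)
  })
  attr(images, "prep_params") <- list(
    target_size = target_size, low_pct = low_pct, high_pct = high_pct,
    background_threshold = background_threshold, white_point = white_point,
    method = method
  )
  images
}
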