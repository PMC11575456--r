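#' Configuration for hair compositing
#'
#' The hairy image is produced by alpha-blending a hair color over the clean
#' image, with the blurred mask as the alpha channel. The hair color is
#' derived from the base image itself (mean of its darkest pixels) and then
#' darkened, if necessary, until its luminance differs from the image's
#' median skin luminance by at least `min_contrast` - a procedural stand-in
#' for a learned hair-texture synthesizer that honours the same contracts:
#' color taken from the base image, and guaranteed hair/skin contrast.
#'
#' @param color_percentile luminance percentile (0-100) below which base
#'   pixels are averaged to pick the hair color. Default 10 (dark
#'   structures).
#' @param min_contrast minimum absolute luminance difference between hair
#'   color and median skin luminance, in \[0, 1). Default 0.15.
#' @param color_jitter half-width of the uniform per-channel jitter added to
#'   the hair color (applied before the contrast clamp). Default 0.05.
#' @param per_strand give each strand an independently jittered color
#'   (requires strand metadata on the mask). Default `FALSE`.
#' @return an object of class `composite_config`.
#' @export
composite_config <- function(color_percentile = 10, min_contrast = 0.15,
                             color_jitter = 0.05, per_strand = FALSE) {
  stopifnot(color_percentile > 0, color_percentile < 100,
            min_contrast >= 0, min_contrast < 1, color_jitter >= 0)
  structure(list(color_percentile = color_percentile,
                 min_contrast = min_contrast,
                 color_jitter = color_jitter,
                 per_strand = isTRUE(per_strand)),
            class = "composite_config")
}

#' Derive a hair color from a clean base image
#'
#' Returns the mean color of the pixels at or below the `color_percentile`
#' of luminance, jittered per channel, then darkened if needed so that its
#' luminance differs from the image's median luminance by at least
#' `min_contrast`.
#'
#' @param clean RGB array `H x W x 3` in \[0, 1\].
#' @param config a [composite_config()].
#' @param seed optional integer seed for the jitter.
#' @return length-3 RGB vector in \[0, 1\].
#' @export
derive_hair_color <- function(clean, config = composite_config(),
                              seed = NULL) {
  if (length(clean) == 0) stop("empty image")
  stopifnot(length(dim(clean)) == 3)
  with_seed(seed, {
    lum <- luminance(clean)
    thr <- quantile(lum, config$color_percentile / 100, names = FALSE)
    sel <- lum <= thr
    col <- vapply(1:3, function(ch) mean(clean[, , ch][sel]), 0)
    if (config$color_jitter > 0)
      col <- clamp(col + runif(3, -config$color_jitter, config$color_jitter))
    med <- median(lum)
    enforce_contrast(col, med, config$min_contrast)
  })
}

# darken col until |luma(col) - skin_luma| >= min_contrast (clamped at black)
enforce_contrast <- function(col, skin_luma, min_contrast) {
  w <- c(0.299, 0.587, 0.114)
  l <- sum(w * col)
  if (abs(l - skin_luma) >= min_contrast) return(col)
  target <- max(skin_luma - min_contrast, 0)
  if (l <= 1e-9) return(rep(target, 3))
  clamp(col * target / l)
}

#' Composite a hair mask over a clean image
#'
#' Produces the hairy image `(1 - m) * clean + m * hair_color` per pixel,
#' where `m` is the soft mask value, and returns the paired sample used for
#' training and evaluation. Outside the mask support the hairy image is
#' bit-identical to the clean image.
#'
#' @param clean RGB array `H x W x 3` in \[0, 1\].
#' @param mask a [hair_mask] or numeric matrix of the same spatial size.
#' @param config a [composite_config()].
#' @param seed optional integer seed (color jitter, per-strand colors).
#' @return an object of class `paired_sample`: list with `clean`, `hairy`,
#'   `mask` (numeric matrix) and `meta` (hair color(s), config echo).
#' @export
composite <- function(clean, mask, config = composite_config(), seed = NULL) {
  m <- if (inherits(mask, "hair_mask")) mask$values else mask
  if (!all(dim(clean)[1:2] == dim(m)))
    stop("clean image and mask sizes differ")
  with_seed(seed, {
    base_col <- derive_hair_color(clean, config)
    colfield <- NULL
    if (config$per_strand && inherits(mask, "hair_mask") &&
        mask$strand_count > 0) {
      colfield <- strand_color_field(mask, dim(m), base_col, config)
    }
    hairy <- clean
    for (ch in 1:3) {
      colc <- if (is.null(colfield)) base_col[ch] else colfield[, , ch]
      hairy[, , ch] <- (1 - m) * clean[, , ch] + m * colc
    }
    structure(list(clean = clean, hairy = clamp(hairy), mask = m,
                   meta = list(hair_color = base_col,
                               per_strand = config$per_strand,
                               min_contrast = config$min_contrast,
                               n_hairs = if (inherits(mask, "hair_mask"))
                                 mask$strand_count else NA_integer_)),
              class = "paired_sample")
  })
}

# per-pixel color map: each strand gets an independently jittered color;
# pixels reached only by the blur halo keep the base color
strand_color_field <- function(mask, dims, base_col, config) {
  scale <- dims[1] / mask$working_size
  field <- array(rep(base_col, each = prod(dims)), dim = c(dims, 3))
  best <- matrix(0, dims[1], dims[2])
  for (s in mask$strand_specs) {
    sp <- strand_spec(s$control_points * scale,
                      max(s$thickness * scale, 1), s$arc_length * scale)
    foot <- strand_footprint(dims, sp)
    col <- clamp(base_col + runif(3, -config$color_jitter, config$color_jitter))
    upd <- foot > best
    for (ch in 1:3) {
      f <- field[, , ch]
      f[upd] <- col[ch]
      field[, , ch] <- f
    }
    best <- pmax(best, foot)
  }
  field
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample> %d x %d, %s hair(s), mask support %.1f%%\n",
              dim(x$clean)[1], dim(x$clean)[2],
              ifelse(is.na(x$meta$n_hairs), "?", x$meta$n_hairs),
              100 * mean(x$mask > 0)))
  invisible(x)
}
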