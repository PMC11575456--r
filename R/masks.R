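#' Configuration for procedural hair-mask generation
#'
#' Hair strands are cubic Bezier curves with four control points, rasterized
#' with coverage-based anti-aliasing and softened with a Gaussian blur. Strand
#' geometry (length in pixels) is defined on a square working canvas of side
#' `working_size`; the finished mask is downscaled to `canvas_size` with
#' bilinear interpolation so that the 100-900 px length range stays meaningful
#' on a 256 px output canvas.
#'
#' @param canvas_size integer `(height, width)` of the output mask.
#' @param num_hairs_range integer interval; the strand count per mask is drawn
#'   uniformly from it. Default 1-40.
#' @param length_range real interval of strand arc lengths in working-canvas
#'   pixels. Default 100-900.
#' @param thickness_range integer interval of stroke thicknesses in pixels.
#'   Default 1-4.
#' @param blur_sigma Gaussian blur standard deviation in working-canvas
#'   pixels. Default 0.8, small enough that 1 px strands keep a bright
#'   centerline.
#' @param curve_samples number of parameter values used to polygonize each
#'   Bezier curve (also the resolution of the arc-length measurement).
#' @param working_size side of the square canvas strands are drawn on before
#'   downscaling. Default 1024.
#' @param margin_frac control points may fall this fraction of the working
#'   size outside the canvas, so strands can enter and leave the frame.
#' @return an object of class `mask_gen_config`.
#' @export
mask_gen_config <- function(canvas_size = c(256L, 256L),
                            num_hairs_range = c(1L, 40L),
                            length_range = c(100, 900),
                            thickness_range = c(1L, 4L),
                            blur_sigma = 0.8,
                            curve_samples = 100L,
                            working_size = 1024L,
                            margin_frac = 0.08) {
  stopifnot(length(canvas_size) == 2, all(canvas_size >= 8))
  if (length(num_hairs_range) != 2 || num_hairs_range[1] > num_hairs_range[2])
    stop("num_hairs_range must be a non-empty interval")
  if (num_hairs_range[1] < 1)
    stop("num_hairs_range must not contain values below 1")
  stopifnot(length_range[1] > 0, length_range[1] <= length_range[2],
            thickness_range[1] >= 1, thickness_range[1] <= thickness_range[2],
            blur_sigma > 0, curve_samples >= 2, working_size >= max(canvas_size))
  structure(list(canvas_size = as.integer(canvas_size),
                 num_hairs_range = as.integer(num_hairs_range),
                 length_range = as.numeric(length_range),
                 thickness_range = as.integer(thickness_range),
                 blur_sigma = blur_sigma,
                 curve_samples = as.integer(curve_samples),
                 working_size = as.integer(working_size),
                 margin_frac = margin_frac),
            class = "mask_gen_config")
}

#' Evaluate a cubic Bezier curve
#'
#' Computes the cubic Bernstein combination
#' `(1-t)^3 P0 + 3(1-t)^2 t P1 + 3(1-t) t^2 P2 + t^3 P3`.
#'
#' @param control_points numeric `4 x 2` matrix of points (row, col).
#' @param t parameter value(s) in \[0, 1\]; vectorized.
#' @return a `length(t) x 2` matrix of curve points.
#' @export
bezier_point <- function(control_points, t) {
  control_points <- as.matrix(control_points)
  if (!all(dim(control_points) == c(4L, 2L)))
    stop("exactly four 2-D control points are required")
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  u <- 1 - t
  b <- cbind(u^3, 3 * u^2 * t, 3 * u * t^2, t^3)
  b %*% control_points
}

# polyline arc length of the sampled curve
bezier_arc_length <- function(control_points, curve_samples) {
  p <- bezier_point(control_points, seq(0, 1, length.out = curve_samples))
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Strand specification
#'
#' @param control_points `4 x 2` matrix, (row, col) pixel coordinates, 0-based.
#' @param thickness stroke thickness in pixels (integer, 1-4 by default).
#' @param arc_length arc length of the sampled polyline in pixels.
#' @return an object of class `strand_spec`.
#' @export
strand_spec <- function(control_points, thickness, arc_length) {
  structure(list(control_points = as.matrix(control_points),
                 thickness = as.numeric(thickness),
                 arc_length = as.numeric(arc_length)),
            class = "strand_spec")
}

#' Draw a random strand specification
#'
#' Control points are drawn uniformly on the margin-extended working canvas,
#' the polyline arc length is measured, and the control polygon is rescaled
#' about its centroid to a target length drawn uniformly from
#' `length_range` - so the length marginal is exactly uniform and no
#' rejection loop is needed. Thickness is drawn uniformly from
#' `thickness_range`. Uses the current RNG state.
#'
#' @param config a [mask_gen_config()].
#' @return a [strand_spec].
#' @export
sample_strand_spec <- function(config) {
  stopifnot(inherits(config, "mask_gen_config"))
  s <- config$working_size
  m <- config$margin_frac * s
  repeat {
    cp <- matrix(runif(8, -m, s - 1 + m), 4L, 2L)
    len <- bezier_arc_length(cp, config$curve_samples)
    if (len > 1e-6) break
  }
  target <- runif(1, config$length_range[1], config$length_range[2])
  centroid <- matrix(colMeans(cp), 4L, 2L, byrow = TRUE)
  cp <- centroid + (cp - centroid) * (target / len)
  tv <- seq(config$thickness_range[1], config$thickness_range[2])
  thick <- if (length(tv) == 1L) tv else sample(tv, 1L)
  strand_spec(cp, thick, target)
}

#' Rasterize one strand onto a canvas
#'
#' The curve is polygonized at `curve_samples` parameter values and each
#' segment is drawn as a stroke of width `thickness` with coverage-style
#' anti-aliasing: a pixel's value is `clamp(0.5 + (thickness/2 - d), 0, 1)`
#' where `d` is the distance from the pixel center to the segment, i.e. a
#' signed-distance falloff over one pixel around the stroke edge. The strand
#' footprint (maximum over segments) is added to the canvas and saturated at
#' 1; pixels outside the canvas are clipped silently.
#'
#' @param canvas numeric matrix with values in \[0, 1\].
#' @param spec a [strand_spec].
#' @param curve_samples number of polyline samples.
#' @return the updated canvas matrix.
#' @export
rasterize_strand <- function(canvas, spec, curve_samples = 100L) {
  stopifnot(is.matrix(canvas))
  foot <- strand_footprint(dim(canvas), spec, curve_samples)
  clamp(canvas + foot, 0, 1)
}

# coverage footprint of a single strand on an H x W grid (0-based pixel
# centers at integer (row, col))
strand_footprint <- function(dims, spec, curve_samples = 100L) {
  h <- dims[1]; w <- dims[2]
  foot <- matrix(0, h, w)
  p <- bezier_point(spec$control_points, seq(0, 1, length.out = curve_samples))
  r <- spec$thickness / 2
  pad <- r + 1.5
  for (k in seq_len(nrow(p) - 1)) {
    a <- p[k, ]; b <- p[k + 1, ]
    r0 <- max(0L, floor(min(a[1], b[1]) - pad))
    r1 <- min(h - 1L, ceiling(max(a[1], b[1]) + pad))
    c0 <- max(0L, floor(min(a[2], b[2]) - pad))
    c1 <- min(w - 1L, ceiling(max(a[2], b[2]) + pad))
    if (r0 > r1 || c0 > c1) next
    ri <- r0:r1; ci <- c0:c1
    ab <- b - a
    ab2 <- sum(ab^2)
    pr <- matrix(ri, length(ri), length(ci))
    pc <- matrix(ci, length(ri), length(ci), byrow = TRUE)
    if (ab2 < 1e-12) {
      d <- sqrt((pr - a[1])^2 + (pc - a[2])^2)
    } else {
      tt <- ((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / ab2
      tt <- clamp(tt, 0, 1)
      d <- sqrt((pr - (a[1] + tt * ab[1]))^2 + (pc - (a[2] + tt * ab[2]))^2)
    }
    cov <- clamp(0.5 + (r - d), 0, 1)
    sub <- foot[ri + 1L, ci + 1L, drop = FALSE]
    foot[ri + 1L, ci + 1L] <- pmax(sub, cov)
  }
  foot
}

new_hair_mask <- function(values, strand_specs, working_size = nrow(values)) {
  structure(list(values = values,
                 strand_count = length(strand_specs),
                 strand_specs = strand_specs,
                 working_size = working_size),
            class = "hair_mask")
}

#' Draw per-mask hair counts
#'
#' Strand counts are uniform on `num_hairs_range` (all integers equally
#' likely), the distribution under which the low/medium/high density bins
#' carry 12.5% / 37.5% / 50% of the samples.
#'
#' @param n number of draws.
#' @param config a [mask_gen_config()].
#' @param seed optional integer seed.
#' @return integer vector of strand counts.
#' @export
sample_hair_counts <- function(n, config = mask_gen_config(), seed = NULL) {
  vals <- seq(config$num_hairs_range[1], config$num_hairs_range[2])
  if (length(vals) == 1L) return(rep(vals, n))
  with_seed(seed, sample(vals, n, replace = TRUE))
}

#' Generate a hair mask
#'
#' Starts from an all-zero working canvas, draws `n` strands (with `n` drawn
#' uniformly from `num_hairs_range`), applies a Gaussian blur of standard
#' deviation `blur_sigma`, clamps to \[0, 1\] and downscales to `canvas_size`.
#'
#' @param config a [mask_gen_config()].
#' @param seed optional integer; when given, the mask is generated from a
#'   local RNG stream seeded with it (bit-identical on repeat calls).
#' @return an object of class `hair_mask` with fields `values`
#'   (`canvas_size` matrix in \[0, 1\]), `strand_count`, `strand_specs`
#'   (working-canvas coordinates) and `working_size`.
#' @export
generate_mask <- function(config = mask_gen_config(), seed = NULL) {
  stopifnot(inherits(config, "mask_gen_config"))
  with_seed(seed, {
    n <- sample_hair_counts(1L, config)
    specs <- vector("list", n)
    s <- config$working_size
    canvas <- matrix(0, s, s)
    for (i in seq_len(n)) {
      specs[[i]] <- sample_strand_spec(config)
      canvas <- clamp(canvas +
                        strand_footprint(c(s, s), specs[[i]],
                                         config$curve_samples), 0, 1)
    }
    canvas <- gaussian_blur(canvas, config$blur_sigma)
    canvas <- clamp(canvas, 0, 1)
    if (!all(dim(canvas) == config$canvas_size)) {
      canvas <- resize_bilinear(canvas, config$canvas_size[1],
                                config$canvas_size[2])
      canvas <- clamp(canvas, 0, 1)
    }
    new_hair_mask(canvas, specs, working_size = s)
  })
}

#' Binarize a hair mask
#'
#' A pixel belongs to the hair set iff its mask value is at least
#' `threshold`. The default 0.1 is deliberately low: after blurring and
#' downscaling, thin strands have low peak intensity, and the losses and
#' detection metrics should see their full footprint.
#'
#' @param mask a [hair_mask] or numeric matrix in \[0, 1\].
#' @param threshold real in (0, 1).
#' @return logical matrix.
#' @export
binarize_mask <- function(mask, threshold = 0.1) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  v <- if (inherits(mask, "hair_mask")) mask$values else mask
  v >= threshold
}

#' @export
print.hair_mask <- function(x, ...) {
  cat(sprintf("<hair_mask> %d x %d, %d strand(s), values in [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$strand_count,
              min(x$values), max(x$values)))
  invisible(x)
}

# Gaussian blur via EBImage (zero-padded borders so strands never wrap)
gaussian_blur <- function(x, sigma) {
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  pad <- r
  h <- nrow(x); w <- ncol(x)
  xp <- matrix(0, h + 2 * pad, w + 2 * pad)
  xp[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- x
  yp <- EBImage::gblur(xp, sigma = sigma, radius = r)
  yp[(pad + 1):(pad + h), (pad + 1):(pad + w)]
}

resize_bilinear <- function(x, h, w) {
  EBImage::resize(x, w = h, h = w, filter = "bilinear")
}
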