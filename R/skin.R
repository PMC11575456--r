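#' Configuration for the synthetic-skin fixture generator
#'
#' Generates minimal procedural dermoscopic lesion images: a skin-tone
#' background with low-frequency shading, plus one darker elliptical lesion
#' whose border radius is perturbed by a smooth periodic function (border
#' irregularity) and whose interior carries fine pigment texture noise.
#' These fixtures stand in for curated hair-free dermoscopy photographs so
#' that the whole pipeline can run offline; they deliberately do not attempt
#' lesion realism.
#'
#' @param canvas_size integer `(height, width)`; default `c(256, 256)`.
#' @param skin_tone length-3 RGB vector in \[0, 1\] or one of the presets
#'   `"light"`, `"medium"`, `"tan"`, `"dark"`.
#' @param lesion_radius_range pixel interval for the lesion semi-axes.
#' @param border_irregularity amplitude (>= 0) of the radial border
#'   perturbation; 0 gives an exact ellipse.
#' @param pigment_noise standard deviation of the per-pixel texture noise
#'   inside the lesion; 0 disables it.
#' @param shading_amp amplitude of the low-frequency background shading.
#' @param edge_softness width in pixels of the lesion border blend; 0 gives
#'   a hard analytic boundary.
#' @return an object of class `synthetic_skin_config`.
#' @export
synthetic_skin_config <- function(canvas_size = c(256L, 256L),
                                  skin_tone = "light",
                                  lesion_radius_range = NULL,
                                  border_irregularity = 0.12,
                                  pigment_noise = 0.035,
                                  shading_amp = 0.03,
                                  edge_softness = 2) {
  stopifnot(length(canvas_size) == 2, all(canvas_size >= 16),
            border_irregularity >= 0, pigment_noise >= 0,
            shading_amp >= 0, edge_softness >= 0)
  if (is.character(skin_tone)) skin_tone <- skin_tone_preset(skin_tone)
  stopifnot(length(skin_tone) == 3, all(skin_tone >= 0 & skin_tone <= 1))
  if (is.null(lesion_radius_range))
    lesion_radius_range <- round(min(canvas_size) * c(0.15, 0.3))
  if (max(lesion_radius_range) * (1 + border_irregularity) >
      min(canvas_size) / 2 - 2)
    stop("lesion does not fit within the canvas")
  structure(list(canvas_size = as.integer(canvas_size),
                 skin_tone = as.numeric(skin_tone),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 border_irregularity = border_irregularity,
                 pigment_noise = pigment_noise,
                 shading_amp = shading_amp,
                 edge_softness = edge_softness),
            class = "synthetic_skin_config")
}

skin_tone_preset <- function(name) {
  tones <- list(light  = c(0.90, 0.75, 0.66),
                medium = c(0.80, 0.62, 0.52),
                tan    = c(0.66, 0.48, 0.39),
                dark   = c(0.45, 0.31, 0.26))
  if (!name %in% names(tones))
    stop("unknown skin tone preset: ", name)
  tones[[name]]
}

#' Generate a synthetic hair-free lesion image
#'
#' @param config a [synthetic_skin_config()].
#' @param seed optional integer seed; identical seeds give identical images.
#' @return RGB array `H x W x 3` in \[0, 1\].
#' @export
generate_synthetic_skin <- function(config = synthetic_skin_config(),
                                    seed = NULL) {
  stopifnot(inherits(config, "synthetic_skin_config"))
  with_seed(seed, {
    h <- config$canvas_size[1]; w <- config$canvas_size[2]
    rr <- matrix(0:(h - 1), h, w)
    cc <- matrix(0:(w - 1), h, w, byrow = TRUE)

    # low-frequency shading: two random sinusoids
    shading <- 0
    if (config$shading_amp > 0) {
      for (i in 1:2) {
        fr <- runif(2, 0.5, 1.5) * 2 * pi
        ph <- runif(2, 0, 2 * pi)
        shading <- shading + sin(fr[1] * rr / h + ph[1]) *
          sin(fr[2] * cc / w + ph[2])
      }
      shading <- config$shading_amp * shading / 2
    }

    # lesion geometry: rotated ellipse, radially perturbed border
    ctr <- c(h, w) / 2 + runif(2, -0.05, 0.05) * c(h, w)
    ax <- runif(2, config$lesion_radius_range[1], config$lesion_radius_range[2])
    rot <- runif(1, 0, pi)
    dx <- (rr - ctr[1]) * cos(rot) + (cc - ctr[2]) * sin(rot)
    dy <- -(rr - ctr[1]) * sin(rot) + (cc - ctr[2]) * cos(rot)
    rho <- sqrt((dx / ax[1])^2 + (dy / ax[2])^2)  # 1 on the ellipse
    pert <- 0
    if (config$border_irregularity > 0) {
      phi <- atan2(dy, dx)
      amp <- runif(4, 0, 1); phs <- runif(4, 0, 2 * pi)
      pert <- 0
      for (k in 1:4) pert <- pert + amp[k] * cos((k + 1) * phi + phs[k])
      pert <- config$border_irregularity * pert / sum(amp)
    }
    boundary <- 1 + pert
    if (config$edge_softness > 0) {
      soft <- config$edge_softness / sqrt(prod(ax))
      alpha <- clamp((boundary - rho) / soft + 0.5, 0, 1)
    } else {
      alpha <- (rho <= boundary) * 1
    }

    pigment <- config$skin_tone * c(0.42, 0.30, 0.34)  # dark brown pigment
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      bg <- config$skin_tone[ch] * (1 + shading)
      les <- pigment[ch] * (1 + 0.3 * shading)
      img[, , ch] <- (1 - alpha) * bg + alpha * les
    }
    if (config$pigment_noise > 0) {
      noise <- matrix(rnorm(h * w, 0, config$pigment_noise), h, w) * alpha
      for (ch in 1:3) img[, , ch] <- img[, , ch] + noise
    }
    clamp(img)
  })
}
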