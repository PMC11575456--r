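#' Dullrazor-style morphological hair removal baseline
#'
#' The classical pipeline: per RGB channel, grayscale morphological closing
#' with line structuring elements at 0, 45, 90 and 135 degrees; a pixel is
#' flagged as hair when the maximum closing response `closed - original`
#' (over channels and orientations) exceeds `detect_threshold`. The raw
#' mask is cleaned by dropping connected components smaller than
#' `min_component` pixels. Hair pixels are then replaced by linear
#' interpolation between the two nearest non-hair pixels along the normal
#' of the locally dominant hair orientation (the orientation whose line
#' element responded most strongly), and the replaced pixels are smoothed
#' with a median filter.
#'
#' @param image RGB array `H x W x 3` in \[0, 1\].
#' @param line_length length in pixels of the line structuring elements.
#' @param detect_threshold closing-response threshold for hair detection.
#' @param min_component minimum connected-component size kept in the mask.
#' @param median_size median filter window (odd).
#' @param interp_dilate dilation radius applied to the detected mask before
#'   interpolation, so replacement also covers the dark halo around strands.
#' @param max_reach maximum search distance (pixels) for non-hair neighbours.
#' @return list with `cleaned` (RGB array) and `mask` (logical matrix of
#'   detected hair pixels, before dilation).
#' @export
dullrazor <- function(image, line_length = 9L, detect_threshold = 0.1,
                      min_component = 10L, median_size = 5L,
                      interp_dilate = 1L, max_reach = 40L) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  angles <- c(0, 45, 90, 135)
  resp <- array(-Inf, c(h, w, length(angles)))
  for (ai in seq_along(angles)) {
    se <- line_brush(line_length, angles[ai])
    best <- matrix(-Inf, h, w)
    for (ch in 1:3) {
      closed <- EBImage::closing(image[, , ch], se)
      best <- pmax(best, closed - image[, , ch])
    }
    resp[, , ai] <- best
  }
  maxresp <- apply(resp, c(1, 2), max)
  raw <- maxresp > detect_threshold
  mask <- drop_small_components(raw, min_component)
  if (!any(mask))
    return(list(cleaned = image, mask = mask))
  orient <- apply(resp, c(1, 2), which.max)

  interp_mask <- dilate_mask(mask, interp_dilate)
  cleaned <- interpolate_hair(image, interp_mask, orient, angles, max_reach)

  # median-smooth only the replaced pixels
  med <- cleaned
  r <- (median_size - 1L) %/% 2L
  for (ch in 1:3)
    med[, , ch] <- EBImage::medianFilter(clamp(cleaned[, , ch]), size = r)
  sel3 <- array(interp_mask, dim(image))
  cleaned[sel3] <- med[sel3]
  list(cleaned = clamp(cleaned), mask = mask)
}

# line structuring element of the given Euclidean length and angle
# (degrees), trimmed to the bounding box of its support (the trim also
# avoids an EBImage morphology edge case with full-height single-column
# brushes)
line_brush <- function(len, angle) {
  len <- as.integer(len)
  if (len %% 2L == 0L) len <- len + 1L
  r <- (len - 1L) %/% 2L
  m <- matrix(0, len, len)
  th <- angle * pi / 180
  dr <- -sin(th); dc <- cos(th)
  for (t in seq(-r, r, by = 0.5)) {
    i <- round(r + t * dr) + 1L
    j <- round(r + t * dc) + 1L
    if (i >= 1 && i <= len && j >= 1 && j <= len) m[i, j] <- 1
  }
  ri <- range(which(rowSums(m) > 0))
  ci <- range(which(colSums(m) > 0))
  m[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
}

drop_small_components <- function(mask, min_size) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# replace hair pixels by distance-weighted interpolation of the nearest
# non-hair pixels along the normal to the local hair orientation. The line
# element with the strongest closing response is the one bridging the
# strand, i.e. it already points along the hair's normal, so interpolation
# walks in that element's own direction.
interpolate_hair <- function(image, mask, orient, angles, max_reach) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- image
  idx <- which(mask, arr.ind = TRUE)
  normals <- lapply(angles, function(a) {
    th <- a * pi / 180
    c(-sin(th), cos(th))
  })
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    nv <- normals[[orient[i, j]]]
    hit <- list()
    for (dir in c(1, -1)) {
      for (step in seq_len(max_reach)) {
        ii <- round(i + dir * step * nv[1])
        jj <- round(j + dir * step * nv[2])
        if (ii < 1 || ii > h || jj < 1 || jj > w) break
        if (!mask[ii, jj]) {
          hit[[length(hit) + 1]] <- c(ii, jj, step)
          break
        }
      }
    }
    if (length(hit) == 0) next
    if (length(hit) == 1) {
      out[i, j, ] <- image[hit[[1]][1], hit[[1]][2], ]
    } else {
      d1 <- hit[[1]][3]; d2 <- hit[[2]][3]
      v1 <- image[hit[[1]][1], hit[[1]][2], ]
      v2 <- image[hit[[2]][1], hit[[2]][2], ]
      out[i, j, ] <- (d2 * v1 + d1 * v2) / (d1 + d2)
    }
  }
  out
}
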