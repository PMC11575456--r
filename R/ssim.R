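#' Structural similarity index (SSIM)
#'
#' Gaussian-windowed SSIM with the standard constants: an 11x11 window of
#' standard deviation 1.5, `K1 = 0.01`, `K2 = 0.03`, dynamic range `L = 1`.
#' The SSIM map is computed over valid window positions only (no padding)
#' and averaged over positions and channels.
#'
#' @param a,b images: matrices or `H x W x C` arrays in \[0, 1\], same shape.
#' @param window odd window size.
#' @param sigma Gaussian window standard deviation.
#' @param K1,K2 stability constants.
#' @param L dynamic range of the data.
#' @return scalar SSIM; 1 iff the images are identical.
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 L = 1) {
  ab <- check_pair(a, b, window)
  w <- gauss_kernel(window, sigma)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- vapply(seq_len(dim(ab$a)[3]), function(ch) {
    mean(ssim_map(ab$a[, , ch], ab$b[, , ch], w, C1, C2)$S)
  }, 0)
  mean(vals)
}

check_pair <- function(a, b, window) {
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  if (is.matrix(b)) b <- array(b, c(dim(b), 1L))
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  if (min(dim(a)[1:2]) < window)
    stop("image smaller than the SSIM window")
  list(a = a, b = b)
}

gauss_kernel <- function(window = 11L, sigma = 1.5) {
  r <- (window - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# per-channel SSIM map over valid positions, with the intermediates needed
# for the analytic gradient
ssim_map <- function(x, y, w, C1, C2) {
  ux <- cpp_filter2_valid(x, w)
  uy <- cpp_filter2_valid(y, w)
  vx <- cpp_filter2_valid(x * x, w)
  vy <- cpp_filter2_valid(y * y, w)
  cxy <- cpp_filter2_valid(x * y, w)
  sx2 <- vx - ux^2
  sy2 <- vy - uy^2
  sxy <- cxy - ux * uy
  A1 <- 2 * ux * uy + C1
  A2 <- 2 * sxy + C2
  B1 <- ux^2 + uy^2 + C1
  B2 <- sx2 + sy2 + C2
  list(S = A1 * A2 / (B1 * B2), ux = ux, uy = uy,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2)
}

# SSIM and its gradient with respect to the first image. The windowed means
# ux = w*x, vx = w*(x^2), cxy = w*(x*y) are the only places x enters, so the
# chain rule reduces to three adjoint filterings.
ssim_with_grad <- function(x, y, window = 11L, sigma = 1.5, K1 = 0.01,
                           K2 = 0.03, L = 1) {
  ab <- check_pair(x, y, window)
  x <- ab$a; y <- ab$b
  w <- gauss_kernel(window, sigma)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  nch <- dim(x)[3]
  H <- dim(x)[1]; W <- dim(x)[2]
  grad <- array(0, dim(x))
  total <- 0
  for (ch in seq_len(nch)) {
    xc <- x[, , ch]; yc <- y[, , ch]
    m <- ssim_map(xc, yc, w, C1, C2)
    nval <- length(m$S)
    total <- total + mean(m$S)
    inv <- 1 / (m$B1 * m$B2)
    dS_dA1 <- m$A2 * inv
    dS_dB1 <- -m$S / m$B1
    dS_dsx2 <- -m$S / m$B2           # through B2
    dS_dsxy <- 2 * m$A1 * inv        # through A2
    dS_dux <- dS_dA1 * 2 * m$uy + dS_dB1 * 2 * m$ux +
      dS_dsx2 * (-2 * m$ux) + dS_dsxy * (-m$uy)
    dS_dvx <- dS_dsx2
    dS_dcxy <- dS_dsxy
    g <- cpp_filter2_valid_adjoint(dS_dux, w, H, W) +
      2 * xc * cpp_filter2_valid_adjoint(dS_dvx, w, H, W) +
      yc * cpp_filter2_valid_adjoint(dS_dcxy, w, H, W)
    grad[, , ch] <- g / (nval * nch)
  }
  list(value = total / nch, grad = grad)
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' The image pyramid is built by 2x2 average pooling; contrast-structure
#' terms are averaged at every scale and the luminance term enters only at
#' the coarsest scale, with the conventional per-scale exponents
#' `(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)` (renormalized to sum to one
#' when fewer scales are used, so `scales = 1` reduces to plain SSIM).
#'
#' @inheritParams ssim
#' @param scales number of dyadic scales; the coarsest scale must still be
#'   at least as large as the window.
#' @return scalar MS-SSIM in \[0, 1\] for inputs in \[0, 1\].
#' @export
ms_ssim <- function(a, b, scales = 5L, window = 11L, sigma = 1.5,
                    K1 = 0.01, K2 = 0.03, L = 1) {
  ab <- check_pair(a, b, window)
  a <- ab$a; b <- ab$b
  if (min(dim(a)[1:2]) / 2^(scales - 1) < window)
    stop("image too small for the requested number of scales")
  wts <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  if (scales > length(wts)) stop("at most 5 scales are supported")
  wts <- wts[seq_len(scales)] / sum(wts[seq_len(scales)])
  w <- gauss_kernel(window, sigma)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  nch <- dim(a)[3]
  out <- 1
  for (s in seq_len(scales)) {
    mcs <- 0; mssim <- 0
    for (ch in seq_len(nch)) {
      m <- ssim_map(a[, , ch], b[, , ch], w, C1, C2)
      mcs <- mcs + mean(m$A2 / m$B2) / nch
      mssim <- mssim + mean(m$S) / nch
    }
    if (s < scales) {
      out <- out * max(mcs, 0)^wts[s]
      a <- avgpool2_arr(a)
      b <- avgpool2_arr(b)
    } else {
      out <- out * max(mssim, 0)^wts[s]
    }
  }
  out
}

avgpool2_arr <- function(x) {
  h <- floor(dim(x)[1] / 2); w <- floor(dim(x)[2] / 2)
  out <- array(0, c(h, w, dim(x)[3]))
  i1 <- seq_len(h) * 2 - 1; j1 <- seq_len(w) * 2 - 1
  for (ch in seq_len(dim(x)[3])) {
    s <- x[, , ch]
    out[, , ch] <- (s[i1, j1] + s[i1 + 1, j1] + s[i1, j1 + 1] +
                      s[i1 + 1, j1 + 1]) / 4
  }
  out
}
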