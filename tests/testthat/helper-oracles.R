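# Independent brute-force oracles used to cross-check the optimized
# implementations. These deliberately share no code with the package paths
# they verify.

# de Casteljau evaluation of a cubic Bezier by repeated linear interpolation
decasteljau <- function(cp, t) {
  p <- cp
  while (nrow(p) > 1) {
    p <- (1 - t) * p[-nrow(p), , drop = FALSE] + t * p[-1, , drop = FALSE]
  }
  p[1, ]
}

# direct double-loop MSE / MAE
mse_brute <- function(a, b) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  acc / length(a)
}
mae_brute <- function(a, b) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
  acc / length(a)
}

gauss_win_brute <- function(window, sigma) {
  r <- (window - 1) / 2
  g <- outer(-r:r, -r:r, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  g / sum(g)
}

# windowed SSIM by explicit per-position patch statistics
ssim_brute <- function(a, b, window = 11L, sigma = 1.5, K1 = 0.01,
                       K2 = 0.03, L = 1) {
  if (is.matrix(a)) a <- array(a, c(dim(a), 1))
  if (is.matrix(b)) b <- array(b, c(dim(b), 1))
  w <- gauss_win_brute(window, sigma)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  h <- dim(a)[1]; wd <- dim(a)[2]
  vals <- numeric(0)
  for (ch in seq_len(dim(a)[3])) {
    for (i in seq_len(h - window + 1)) {
      for (j in seq_len(wd - window + 1)) {
        pa <- a[i:(i + window - 1), j:(j + window - 1), ch]
        pb <- b[i:(i + window - 1), j:(j + window - 1), ch]
        mx <- sum(w * pa); my <- sum(w * pb)
        sx <- sum(w * pa^2) - mx^2
        sy <- sum(w * pb^2) - my^2
        sxy <- sum(w * pa * pb) - mx * my
        vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                    ((mx^2 + my^2 + C1) * (sx + sy + C2)))
      }
    }
  }
  mean(vals)
}

# brute MS-SSIM: per-scale contrast-structure means from explicit patches,
# 2x2 block-mean pyramid, luminance only at the coarsest scale
msssim_brute <- function(a, b, scales = 2L, window = 11L, sigma = 1.5,
                         K1 = 0.01, K2 = 0.03, L = 1) {
  if (is.matrix(a)) a <- array(a, c(dim(a), 1))
  if (is.matrix(b)) b <- array(b, c(dim(b), 1))
  w <- gauss_win_brute(window, sigma)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  wts <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)[seq_len(scales)]
  wts <- wts / sum(wts)
  halve <- function(x) {
    h <- floor(dim(x)[1] / 2); wd <- floor(dim(x)[2] / 2)
    out <- array(0, c(h, wd, dim(x)[3]))
    for (ch in seq_len(dim(x)[3]))
      for (i in seq_len(h))
        for (j in seq_len(wd))
          out[i, j, ch] <- mean(x[(2 * i - 1):(2 * i),
                                  (2 * j - 1):(2 * j), ch])
    out
  }
  res <- 1
  for (s in seq_len(scales)) {
    cs_vals <- s_vals <- numeric(0)
    for (ch in seq_len(dim(a)[3])) {
      h <- dim(a)[1]; wd <- dim(a)[2]
      for (i in seq_len(h - window + 1)) {
        for (j in seq_len(wd - window + 1)) {
          pa <- a[i:(i + window - 1), j:(j + window - 1), ch]
          pb <- b[i:(i + window - 1), j:(j + window - 1), ch]
          mx <- sum(w * pa); my <- sum(w * pb)
          sx <- sum(w * pa^2) - mx^2
          sy <- sum(w * pb^2) - my^2
          sxy <- sum(w * pa * pb) - mx * my
          cs <- (2 * sxy + C2) / (sx + sy + C2)
          l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
          cs_vals <- c(cs_vals, cs)
          s_vals <- c(s_vals, l * cs)
        }
      }
    }
    if (s < scales) {
      res <- res * max(mean(cs_vals), 0)^wts[s]
      a <- halve(a); b <- halve(b)
    } else {
      res <- res * max(mean(s_vals), 0)^wts[s]
    }
  }
  res
}

# brute-force grayscale morphology with a flat (possibly rectangular)
# structuring element
morph_brute <- function(x, se, op) {
  h <- nrow(x); w <- ncol(x)
  rh <- (nrow(se) - 1) / 2
  rw <- (ncol(se) - 1) / 2
  pad <- if (op == "min") Inf else -Inf
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    best <- pad
    for (di in -rh:rh) for (dj in -rw:rw) {
      if (se[di + rh + 1, dj + rw + 1] == 0) next
      ii <- i + di; jj <- j + dj
      v <- if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) x[ii, jj] else pad
      best <- if (op == "min") min(best, v) else max(best, v)
    }
    out[i, j] <- best
  }
  out
}
erode_brute <- function(x, se) morph_brute(x, se, "min")
dilate_brute <- function(x, se) morph_brute(x, se, "max")
closing_brute <- function(x, se) erode_brute(dilate_brute(x, se), se)
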