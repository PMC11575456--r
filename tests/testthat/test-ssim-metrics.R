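test_that("mse and mae match a brute-force oracle", {
  set.seed(41)
  a <- rand_img(8); b <- rand_img(8)
  expect_equal(mse(a, a), 0)
  expect_equal(mae(a, a), 0)
  expect_equal(mse(a + 0.1, a), 0.01, tolerance = 1e-12)
  expect_equal(mae(a + 0.1, a), 0.1, tolerance = 1e-12)
  expect_equal(mse(a, b), mse_brute(a, b), tolerance = 1e-12)
  expect_equal(mae(a, b), mae_brute(a, b), tolerance = 1e-12)
  expect_error(mse(a, rand_img(4)), "differ")
})

test_that("ssim agrees with a brute-force windowed implementation", {
  set.seed(42)
  for (i in 1:5) {
    pr <- rand_img_pair(24, ch = 1, noise = 0.15)
    expect_equal(ssim(pr$a[, , 1], pr$b[, , 1]),
                 ssim_brute(pr$a[, , 1], pr$b[, , 1]), tolerance = 1e-6)
  }
  pr <- rand_img_pair(24, ch = 3)
  expect_equal(ssim(pr$a, pr$b), ssim_brute(pr$a, pr$b), tolerance = 1e-6)
})

test_that("ssim is 1 for identical images, symmetric, and bounded", {
  img <- tiny_skin(32, seed = 51)
  expect_equal(ssim(img, img), 1)
  set.seed(52)
  other <- rand_img(32)
  expect_equal(ssim(img, other), ssim(other, img), tolerance = 1e-12)
  expect_lte(ssim(img, other), 1)
  expect_error(ssim(rand_img(8), rand_img(8)), "window")
})

test_that("ms_ssim matches the brute oracle and collapses to ssim at 1 scale", {
  set.seed(43)
  pr <- rand_img_pair(32, ch = 1)
  a <- pr$a[, , 1]; b <- pr$b[, , 1]
  expect_equal(ms_ssim(a, a, scales = 2), 1)
  expect_equal(ms_ssim(a, b, scales = 2), msssim_brute(a, b, scales = 2),
               tolerance = 1e-5)
  expect_equal(ms_ssim(a, b, scales = 1), ssim(a, b), tolerance = 1e-12)
  expect_error(ms_ssim(a, b, scales = 3), "too small")
})

test_that("ms_ssim degrades monotonically with increasing noise", {
  img <- tiny_skin(64, seed = 53)
  set.seed(54)
  noise <- array(rnorm(length(img)), dim(img))
  levels <- seq(0.01, 0.4, length.out = 20)
  vals <- vapply(levels, function(s)
    ms_ssim(img, clamp(img + s * noise), scales = 2), 0)
  # average monotone decrease (pairwise, allowing tiny local noise)
  expect_lt(mean(diff(vals)), 0)
  expect_true(vals[20] < vals[1])
  expect_gt(mean(diff(vals) < 1e-3), 0.8)
})

test_that("sigmoid-free SSIM gradient matches finite differences", {
  set.seed(55)
  x <- array(runif(20 * 20, 0.2, 0.8), c(20, 20, 1))
  y <- array(runif(20 * 20), c(20, 20, 1))
  sg <- hairbench:::ssim_with_grad(x, y)
  expect_equal(sg$value, ssim(x, y), tolerance = 1e-12)
  h <- 1e-6
  idx <- sample(length(x), 15)
  num <- vapply(idx, function(i) {
    x1 <- x; x1[i] <- x1[i] + h
    x2 <- x; x2[i] <- x2[i] - h
    (ssim(x1, y) - ssim(x2, y)) / (2 * h)
  }, 0)
  expect_equal(num, sg$grad[idx], tolerance = 1e-5)
})

test_that("near-mask precision/recall/F1 follow their definitions", {
  pair <- tiny_pair(64, seed = 61, n_hairs = 6)
  truth <- binarize_mask(pair$mask)

  # no change at all -> recall 0
  r0 <- prf_near_mask(pair$hairy, pair$hairy, pair$mask)
  expect_equal(r0$recall, 0)

  # perfect detector: change exactly the true hair set
  removed <- pair$hairy
  for (ch in 1:3) {
    s <- removed[, , ch]
    s[truth] <- clamp(s[truth] + 0.5)
    removed[, , ch] <- s
  }
  r1 <- prf_near_mask(removed, pair$hairy, pair$mask)
  expect_equal(r1$precision, 1)
  expect_equal(r1$recall, 1)
  expect_equal(r1$f1, 1)

  # empty ground truth is flagged and recall reported as 0
  r2 <- prf_near_mask(removed, pair$hairy, matrix(0.001, 64, 64))
  expect_true(r2$empty_truth)
  expect_equal(r2$recall, 0)
})

test_that("f1 is the harmonic mean of precision and recall", {
  expect_equal(f1_score(0.6916, 0.8678),
               2 * 0.6916 * 0.8678 / (0.6916 + 0.8678), tolerance = 1e-12)
  # consistent with the reported removal-model summary at print precision
  # (their mean F1 is a per-image average, not the harmonic mean of the
  # printed means, hence the ~2e-4 gap)
  expect_equal(f1_score(0.6916, 0.8678), 0.7699, tolerance = 3e-4)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0.5, 0), 0)
})

test_that("precision is non-decreasing in the dilation radius", {
  pair <- tiny_pair(64, seed = 62, n_hairs = 8)
  set.seed(63)
  # noisy detector: true changes plus scattered false positives
  removed <- pair$hairy
  truth <- binarize_mask(pair$mask)
  fp <- matrix(runif(64 * 64) > 0.97, 64, 64)
  sel <- truth | fp
  for (ch in 1:3) {
    s <- removed[, , ch]
    s[sel] <- clamp(s[sel] + 0.3)
    removed[, , ch] <- s
  }
  prec <- vapply(c(0, 1, 2, 4, 8), function(r)
    prf_near_mask(removed, pair$hairy, pair$mask, dilation_radius = r)$precision,
    0)
  expect_true(all(diff(prec) >= 0))
})
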