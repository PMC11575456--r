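make_imgs <- function(seed = 1, h = 24) {
  set.seed(seed)
  list(p = rand_img(h), t = rand_img(h),
       hair = matrix(runif(h * h) > 0.7, h, h))
}

test_that("hair and non-hair losses are masked MSEs with empty-set conventions", {
  im <- make_imgs()
  expect_equal(loss_hair(im$t, im$t, im$hair), 0)
  expect_equal(loss_non_hair(im$t, im$t, im$hair), 0)
  none <- matrix(FALSE, 24, 24)
  expect_equal(loss_hair(im$p, im$t, none), 0)
  expect_equal(loss_non_hair(im$p, im$t, !none), 0)

  # single hair pixel, error 0.4 on every channel -> 0.16
  p <- array(0.5, c(8, 8, 3)); t <- p
  hair <- matrix(FALSE, 8, 8); hair[3, 3] <- TRUE
  t[3, 3, ] <- 0.1
  expect_equal(loss_hair(p, t, hair), 0.16)

  # uniform offset of 0.1 on a hair-free image -> non-hair loss 0.01
  expect_equal(loss_non_hair(p + 0.1, p, matrix(FALSE, 8, 8)), 0.01)
  expect_error(loss_hair(p, array(0, c(4, 4, 3)), hair), "differ")
})

test_that("normalized loss is the hair error relative to the whole image", {
  # 2x2 single-channel toy: one hair pixel with error 0.2 -> 0.04 / 4
  p <- array(0, c(2, 2, 1)); t <- p
  hair <- matrix(FALSE, 2, 2); hair[1, 2] <- TRUE
  t[1, 2, 1] <- 0.2
  expect_equal(loss_normalized(p, t, hair), 0.01)

  im <- make_imgs(4)
  expect_equal(loss_normalized(im$p, im$t, im$hair),
               loss_hair(im$p, im$t, im$hair) * sum(im$hair) / (24 * 24))
  expect_lte(loss_normalized(im$p, im$t, im$hair),
             loss_hair(im$p, im$t, im$hair))
})

test_that("SSIM loss vanishes for identical images and is large for inversion", {
  im <- make_imgs(5, h = 32)
  expect_equal(loss_ssim(im$t, im$t), 0)
  expect_equal(loss_ssim(array(0.3, c(16, 16, 3)), array(0.3, c(16, 16, 3))),
               0)
  tex <- tiny_skin(32, seed = 12)
  expect_gt(loss_ssim(1 - tex, tex), 0.5)
})

test_that("total variation is the mean absolute neighbour difference", {
  expect_equal(loss_tv(array(0.7, c(10, 10, 3))), 0)
  m <- matrix(c(0, 0, 1, 1), 2, 2)  # [[0,1],[0,1]] row-wise
  expect_equal(loss_tv(m), 0.5)
  im <- rand_img(12)
  expect_equal(loss_tv(0.4 * im), 0.4 * loss_tv(im))
})

test_that("the composite objective is the weighted sum of its components", {
  comps <- structure(list(hair = 0.1, non_hair = 0.2, normalized = 0.3,
                          ssim_loss = 0.1, tv = 0.05),
                     class = "loss_components")
  expect_equal(total_loss(comps, loss_weights(1, 1, 1, 1, 1)), 0.75)
  ones <- structure(list(hair = 1, non_hair = 1, normalized = 1,
                         ssim_loss = 1, tv = 1), class = "loss_components")
  expect_equal(total_loss(ones, preset_weights("tuned")), 7.8)
  zero <- structure(lapply(ones, function(x) 0), class = "loss_components")
  expect_equal(total_loss(zero, loss_weights(9, 9, 9, 9, 9)), 0)
  expect_error(loss_weights(-1, 1, 1, 1, 1), "non-negative")

  # linearity in each component and weight
  im <- make_imgs(7, h = 16)
  c1 <- loss_components(im$p, im$t, im$hair)
  w <- as.numeric(preset_weights("tuned"))
  manual <- sum(w * c(c1$hair, c1$non_hair, c1$normalized, c1$ssim_loss,
                      c1$tv))
  expect_equal(total_loss(c1, preset_weights("tuned")), manual)
  expect_equal(total_loss(c1, loss_weights(2 * w[1], w[2], w[3], w[4], w[5])),
               manual + w[1] * c1$hair)
})

test_that("identical prediction leaves only the TV floor", {
  img <- tiny_skin(32, seed = 9)
  hair <- matrix(runif(32 * 32) > 0.8, 32, 32)
  comps <- loss_components(img, img, hair)
  expect_equal(comps$hair, 0)
  expect_equal(comps$non_hair, 0)
  expect_equal(comps$normalized, 0)
  expect_equal(comps$ssim_loss, 0)
  w <- preset_weights("tuned")
  expect_equal(total_loss(comps, w), 0.5 * loss_tv(img))
})

test_that("all components are non-negative on random inputs", {
  set.seed(31)
  for (i in 1:10) {
    p <- rand_img(16); t <- rand_img(16)
    hair <- matrix(runif(256) > runif(1, 0.2, 0.9), 16, 16)
    comps <- loss_components(p, t, hair)
    expect_true(all(unlist(comps) >= 0))
  }
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(17)
  p <- array(runif(16 * 16 * 3, 0.2, 0.8), c(16, 16, 3))
  t <- rand_img(16)
  hair <- matrix(runif(256) > 0.7, 16, 16)
  w <- preset_weights("tuned")
  lg <- hairbench:::composite_loss_grad(p, t, hair, w)
  expect_equal(lg$total, total_loss(loss_components(p, t, hair), w),
               tolerance = 1e-12)
  h <- 1e-6
  idx <- sample(length(p), 25)
  num <- vapply(idx, function(i) {
    p1 <- p; p1[i] <- p1[i] + h
    p2 <- p; p2[i] <- p2[i] - h
    (hairbench:::composite_loss_grad(p1, t, hair, w)$total -
       hairbench:::composite_loss_grad(p2, t, hair, w)$total) / (2 * h)
  }, 0)
  expect_equal(num, lg$grad[idx], tolerance = 1e-5)
})
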