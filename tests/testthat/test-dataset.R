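test_that("synthetic skin is deterministic, darker inside the lesion", {
  cfg <- synthetic_skin_config(canvas_size = c(64, 64))
  a <- generate_synthetic_skin(cfg, seed = 5)
  b <- generate_synthetic_skin(cfg, seed = 5)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("degenerate config yields an exact analytic ellipse", {
  cfg <- synthetic_skin_config(canvas_size = c(64, 64),
                               border_irregularity = 0, pigment_noise = 0,
                               shading_amp = 0, edge_softness = 0,
                               lesion_radius_range = c(12, 12))
  img <- generate_synthetic_skin(cfg, seed = 8)
  # classify by luminance: lesion pigment is strictly darker than the skin
  lum <- luminance(img)
  lesion <- lum < (max(lum) + min(lum)) / 2
  # recover the analytic ellipse from the config's own draw sequence
  set.seed(8)
  ctr <- c(64, 64) / 2 + runif(2, -0.05, 0.05) * c(64, 64)
  ax <- runif(2, 12, 12)
  rot <- runif(1, 0, pi)
  rr <- matrix(0:63, 64, 64); cc <- t(rr)
  dx <- (rr - ctr[1]) * cos(rot) + (cc - ctr[2]) * sin(rot)
  dy <- -(rr - ctr[1]) * sin(rot) + (cc - ctr[2]) * cos(rot)
  inside <- sqrt((dx / ax[1])^2 + (dy / ax[2])^2) <= 1
  expect_identical(lesion, inside)
})

test_that("lesion interior is darker than the surrounding skin on average", {
  for (seed in 1:3) {
    cfg <- synthetic_skin_config(canvas_size = c(64, 64))
    img <- generate_synthetic_skin(cfg, seed = seed)
    lum <- luminance(img)
    ctr_patch <- lum[29:36, 29:36]        # lesion is centered
    border_patch <- lum[c(1:4, 61:64), ]  # canvas edge is background
    expect_lt(mean(ctr_patch), mean(border_patch))
  }
})

test_that("density classes follow the 1-5 / 6-20 / 21-40 bins", {
  expect_identical(classify_density(c(1, 5, 6, 20, 21, 40)),
                   c("low", "low", "medium", "medium", "high", "high"))
  expect_error(classify_density(0), "\\[1, 40\\]")
  expect_error(classify_density(41), "\\[1, 40\\]")
})

test_that("train/test split uses ceiling and stays disjoint", {
  mk <- function(n) data.frame(sample_id = sprintf("s%04d", 1:n))
  m <- split_train_test(mk(1064), 0.8, seed = 1)
  expect_identical(sum(m$split == "train"), 852L)
  expect_identical(sum(m$split == "test"), 212L)
  m <- split_train_test(mk(10), 0.8, seed = 1)
  expect_identical(sum(m$split == "train"), 8L)
  m <- split_train_test(mk(5), 0.8, seed = 1)
  expect_identical(sum(m$split == "train"), 4L)
  expect_identical(sum(m$split == "test"), 1L)
  expect_length(intersect(m$sample_id[m$split == "train"],
                          m$sample_id[m$split == "test"]), 0)
  expect_error(split_train_test(data.frame(sample_id = character(0))),
               "empty")
  expect_error(split_train_test(mk(5), 1.2), "\\(0, 1\\)")

  # training size is non-decreasing in N at fixed fraction
  sizes <- vapply(5:60, function(n)
    sum(split_train_test(mk(n), 0.8, seed = 2)$split == "train"), 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("samples sharing a clean image stay on one side of the split", {
  m <- data.frame(sample_id = sprintf("s%03d", 1:100),
                  clean_id = rep(sprintf("c%02d", 1:10), each = 10))
  m <- split_train_test(m, 0.8, seed = 3)
  tab <- table(m$clean_id, m$split)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("build_dataset writes a reproducible, self-consistent manifest", {
  out1 <- file.path(tempdir(), "ds1"); out2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(out1, out2), recursive = TRUE), add = TRUE)
  cfg <- tiny_mask_config(32, 128)
  man1 <- build_dataset(out1, 4, mask_config = cfg, seed = 99)
  man2 <- build_dataset(out2, 4, mask_config = cfg, seed = 99)
  expect_identical(nrow(man1), 4L)
  expect_identical(man1$n_hairs, man2$n_hairs)
  expect_identical(man1$density_class, classify_density(man1$n_hairs))
  expect_identical(man1$split, man2$split)
  for (i in 1:4) {
    s <- load_paired_sample(man1[i, ])
    # outside the (8-bit quantized) mask support, hairy and clean may
    # differ by at most one quantization step
    diff <- abs(s$hairy - s$clean)
    zero <- array(s$mask == 0, dim(diff))
    expect_lte(max(diff[zero], 0), 1 / 255 + 1e-12)
    s2 <- load_paired_sample(man2[i, ])
    expect_identical(s$hairy, s2$hairy)
  }
  # manifest CSV round-trips losslessly
  back <- read_manifest(file.path(out1, "manifest.csv"))
  rownames(back) <- rownames(man1) <- NULL
  expect_identical(back, man1)
})
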