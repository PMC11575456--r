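test_that("bezier_point matches endpoints and the de Casteljau oracle", {
  cp <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  expect_equal(drop(bezier_point(cp, 0)), cp[1, ])
  expect_equal(drop(bezier_point(cp, 1)), cp[4, ])
  expect_equal(drop(bezier_point(cp, 0.5)), c(0.5, 0.75))
  set.seed(101)
  for (i in 1:200) {
    cp <- matrix(runif(8, -50, 50), 4, 2)
    t <- runif(1)
    expect_equal(drop(bezier_point(cp, t)), decasteljau(cp, t),
                 tolerance = 1e-9)
  }
  expect_error(bezier_point(cp, 1.5), "\\[0, 1\\]")
  expect_error(bezier_point(cp[1:3, ], 0.5), "four")
})

test_that("collinear control points keep the curve on the P0-P3 segment", {
  set.seed(102)
  for (i in 1:20) {
    p0 <- runif(2, -10, 10)
    dir <- runif(2, -1, 1)
    cp <- rbind(p0, p0 + 0.3 * dir, p0 + 0.7 * dir, p0 + dir)
    pts <- bezier_point(cp, seq(0, 1, length.out = 25))
    # distance from each point to the segment p0 -> p0+dir
    ab <- dir / sum(dir^2)
    tt <- (sweep(pts, 2, p0) %*% ab)
    tt <- pmin(pmax(tt, 0), 1)
    proj <- sweep(tt %*% rbind(dir), 2, p0, "+")
    expect_lt(max(sqrt(rowSums((pts - proj)^2))), 1e-6)
  }
})

test_that("sampled strands are deterministic with uniform thickness and in-range lengths", {
  cfg <- mask_gen_config()
  set.seed(5)
  s1 <- sample_strand_spec(cfg)
  set.seed(5)
  s2 <- sample_strand_spec(cfg)
  expect_identical(s1, s2)

  set.seed(6)
  specs <- replicate(2000, sample_strand_spec(cfg), simplify = FALSE)
  lens <- vapply(specs, `[[`, 0, "arc_length")
  expect_true(all(lens >= 100 & lens <= 900))
  # stated length is the measured polyline length (rescaling is exact)
  measured <- vapply(specs[1:50], function(s)
    hairbench:::bezier_arc_length(s$control_points, cfg$curve_samples), 0)
  expect_equal(measured, lens[1:50], tolerance = 1e-9)

  thick <- vapply(specs, `[[`, 0, "thickness")
  freq <- as.numeric(table(factor(thick, levels = 1:4))) / length(thick)
  se <- sqrt(0.25 * 0.75 / length(thick))
  expect_true(all(abs(freq - 0.25) <= 3 * se))
})

test_that("rasterization covers the stroke footprint and clips silently", {
  # degenerate strand: all control points equal -> disc of diameter ~ thickness
  canvas <- matrix(0, 21, 21)
  sp <- strand_spec(matrix(10, 4, 2), thickness = 4, arc_length = 0)
  out <- rasterize_strand(canvas, sp)
  expect_gt(out[11, 11], 0.99)
  expect_equal(out[11, 18], 0)          # 7 px away, well outside radius 2
  expect_gte(sum(out > 0.5), 9)         # a blob, not a point

  # strand entirely outside the canvas leaves it untouched
  far <- strand_spec(matrix(c(100, 120, 140, 160, 100, 120, 140, 160),
                            4, 2), 2, 85)
  expect_identical(rasterize_strand(canvas, far), canvas)

  # straight horizontal hair of thickness 1: centerline >= 0.5, rows 2+ away 0
  h <- matrix(0, 15, 30)
  sp <- strand_spec(rbind(c(7, 2), c(7, 10), c(7, 18), c(7, 26)),
                    thickness = 1, arc_length = 24)
  out <- rasterize_strand(h, sp)
  expect_true(all(out[8, 4:26] >= 0.5))  # row 7 (0-based) = index 8
  expect_true(all(out[c(1:5, 11:15), ] == 0))
})

test_that("generate_mask honours forced counts, determinism and [0,1] range", {
  cfg <- tiny_mask_config()
  cfg$num_hairs_range <- c(3L, 3L)
  m <- generate_mask(cfg, seed = 11)
  expect_s3_class(m, "hair_mask")
  expect_identical(m$strand_count, 3L)
  expect_length(m$strand_specs, 3L)
  expect_true(all(m$values >= 0 & m$values <= 1))
  expect_identical(dim(m$values), c(64L, 64L))
  m2 <- generate_mask(cfg, seed = 11)
  expect_identical(m$values, m2$values)
  expect_error(mask_gen_config(num_hairs_range = c(0, 5)), "below 1")
})

test_that("Gaussian blur of an all-zero canvas stays zero", {
  expect_equal(hairbench:::gaussian_blur(matrix(0, 32, 32), 0.8),
               matrix(0, 32, 32))
})

test_that("binarize_mask applies a strict-at-threshold rule", {
  m <- matrix(c(0, 0.4, 0.6, 0), 2, 2)
  expect_identical(binarize_mask(m, 0.5), m >= 0.5)
  expect_false(any(binarize_mask(matrix(0, 4, 4), 0.5)))
  expect_true(all(binarize_mask(matrix(1, 4, 4), 0.5)))
  expect_error(binarize_mask(m, 0), "\\(0, 1\\)")
})

test_that("hair counts are uniform so density bins carry 12.5/37.5/50%", {
  counts <- sample_hair_counts(10000, mask_gen_config(), seed = 9)
  cls <- classify_density(counts)
  p <- c(mean(cls == "low"), mean(cls == "medium"), mean(cls == "high"))
  expected <- c(5, 15, 20) / 40
  se <- sqrt(expected * (1 - expected) / length(counts))
  expect_true(all(abs(p - expected) <= 3 * se))
})

test_that("masks round-trip through PNG + JSON sidecar", {
  cfg <- tiny_mask_config()
  cfg$num_hairs_range <- c(2L, 2L)
  m <- generate_mask(cfg, seed = 3)
  f <- file.path(tempdir(), "mask_rt.png")
  write_mask(m, f)
  back <- read_mask(f)
  expect_s3_class(back, "hair_mask")
  expect_identical(back$strand_count, 2L)
  expect_equal(back$values, round(m$values * 255) / 255, tolerance = 1e-12)
  expect_equal(back$strand_specs[[1]]$control_points,
               m$strand_specs[[1]]$control_points)
  unlink(c(f, sub("png$", "json", f)))
})
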