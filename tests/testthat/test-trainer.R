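small_model <- function(seed = 1) {
  unet_init(unet_config(depth = 2, base_channels = 4,
                        input_size = c(32, 32, 3), init_seed = seed))
}

small_pairs <- function(n = 4, canvas = 32, seed = 80) {
  lapply(seq_len(n), function(i) tiny_pair(canvas, seed = seed + 10 * i))
}

test_that("a zero learning rate reports components without moving parameters", {
  model <- small_model()
  batch <- small_pairs(2)
  cfg <- train_config(learning_rate = 0, iterations = 1, batch_size = 2)
  st <- train_step(model, batch, cfg)
  expect_identical(st$model$params, model$params)
  expect_true(all(unlist(st$components) >= 0))
  expect_equal(st$total, total_loss(st$components, cfg$weights))
})

test_that("train_step is deterministic and descends at a small learning rate", {
  model <- small_model(3)
  batch <- small_pairs(1, seed = 90)
  cfg <- train_config(learning_rate = 1e-5, iterations = 1, batch_size = 1)
  s1 <- train_step(model, batch, cfg)
  s2 <- train_step(model, batch, cfg)
  expect_identical(s1$model$params, s2$model$params)
  expect_error(train_step(model, list(), cfg), "empty")

  loss_of <- function(m) {
    pred <- unet_forward(m, batch[[1]]$hairy)
    total_loss(loss_components(pred, batch[[1]]$clean,
                               binarize_mask(batch[[1]]$mask)),
               cfg$weights)
  }
  expect_lte(loss_of(s1$model), loss_of(model))
})

test_that("train keeps full bookkeeping and ignores the test split", {
  pairs <- small_pairs(4)
  model <- small_model(5)
  cfg <- train_config(iterations = 5, batch_size = 2, seed = 7)
  res <- train(model, pairs, cfg)
  h <- res$history
  expect_identical(nrow(h), 5L)
  expect_identical(h$iter, 1:5)
  w <- as.numeric(cfg$weights)
  expect_equal(h$total,
               w[1] * h$hair + w[2] * h$non_hair + w[3] * h$normalized +
                 w[4] * h$ssim_loss + w[5] * h$tv, tolerance = 1e-9)

  # identical seeds and data reproduce the history exactly
  res2 <- train(small_model(5), pairs, cfg)
  expect_identical(res$history, res2$history)

  # manifest path: test rows point at non-existent files; training must
  # never read them
  dir <- file.path(tempdir(), "train_ds")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  man <- build_dataset(dir, 5, mask_config = tiny_mask_config(32, 128),
                       seed = 4, train_fraction = 0.8)
  test_rows <- man$split == "test"
  expect_identical(sum(test_rows), 1L)
  man$clean_path[test_rows] <- "/nonexistent/never_read.png"
  man$hairy_path[test_rows] <- "/nonexistent/never_read.png"
  model32 <- small_model(6)
  expect_no_error(train(model32, man,
                        train_config(iterations = 2, batch_size = 2)))
  expect_error(train(model32, man[man$split == "nope", ],
                     train_config(iterations = 1)), "empty")
})

test_that("loss histories round-trip through CSV", {
  h <- data.frame(iter = 1:3, hair = runif(3), non_hair = runif(3),
                  normalized = runif(3), ssim_loss = runif(3),
                  tv = runif(3), total = runif(3))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f), add = TRUE)
  write_loss_history(h, f)
  back <- read_loss_history(f)
  expect_equal(back, h, tolerance = 1e-12)
})

test_that("checkpoints are written at the configured cadence", {
  dir <- file.path(tempdir(), "ckpts")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  cfg <- train_config(iterations = 4, batch_size = 1, checkpoint_every = 2,
                      checkpoint_dir = dir)
  res <- train(small_model(8), small_pairs(2), cfg)
  expect_true(dir.exists(file.path(dir, "ckpt_000002")))
  expect_true(dir.exists(file.path(dir, "ckpt_000004")))
  back <- load_model(file.path(dir, "ckpt_000004"))
  expect_identical(back$params, res$model$params)
})

test_that("a single sample can be overfitted", {
  pair <- tiny_pair(64, seed = 77, n_hairs = 5)
  model <- unet_init(unet_config(depth = 3, base_channels = 8,
                                 input_size = c(64, 64, 3), init_seed = 9))
  cfg <- train_config(learning_rate = 2e-3, iterations = 300, batch_size = 1,
                      seed = 10)
  res <- train(model, list(pair), cfg)
  expect_lt(mean(tail(res$history$total, 5)), 0.1 * res$history$total[1])
})
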