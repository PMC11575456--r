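#' Training configuration
#'
#' Adam with the conventional moment decays, a learning rate of 1e-4 and a
#' custom step-based loop: one "iteration" is one optimizer step on one
#' mini-batch (200 by default, mirroring the loss-history protocol).
#'
#' @param learning_rate Adam step size; default 1e-4.
#' @param beta1,beta2,epsilon Adam moment decays and stabiliser.
#' @param iterations number of optimizer steps.
#' @param batch_size samples per step.
#' @param weights a [loss_weights()] vector (default tuned preset).
#' @param mask_threshold binarization threshold defining the hair pixel set
#'   used by the losses (see [binarize_mask()]).
#' @param seed seed for batch shuffling.
#' @param checkpoint_every write a checkpoint every this many steps (0
#'   disables checkpointing).
#' @param checkpoint_dir directory for `ckpt_{iter}` checkpoints.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, iterations = 200L, batch_size = 4L,
                         weights = preset_weights("tuned"),
                         mask_threshold = 0.1, seed = 1L,
                         checkpoint_every = 0L, checkpoint_dir = NULL) {
  stopifnot(learning_rate >= 0, iterations >= 1, batch_size >= 1,
            mask_threshold > 0, mask_threshold < 1)
  if (!inherits(weights, "loss_weights"))
    weights <- do.call(loss_weights, as.list(weights))
  structure(list(learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), weights = weights,
                 mask_threshold = mask_threshold, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

adam_init <- function(params) {
  lapply(params, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_update <- function(params, grads, state, t, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; lr <- cfg$learning_rate
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + cfg$epsilon)
    params[[nm]]$b <- params[[nm]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + cfg$epsilon)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' One training step
#'
#' Forward pass on the batch (hairy images), composite loss against the
#' clean targets with the binarized masks, backpropagation, and one Adam
#' update. Gradients and loss components are averaged over the batch.
#'
#' @param model a `unet_model`.
#' @param batch non-empty list of `paired_sample`s.
#' @param config a [train_config()].
#' @param adam optional Adam state (initialized when `NULL`).
#' @param t step counter for the Adam bias correction (defaults to 1).
#' @return list with `model`, `adam`, `components` (batch means) and
#'   `total`.
#' @export
train_step <- function(model, batch, config = train_config(), adam = NULL,
                       t = 1L) {
  if (length(batch) == 0) stop("empty batch")
  if (is.null(adam)) adam <- adam_init(model$params)
  gacc <- NULL
  comp_acc <- c(hair = 0, non_hair = 0, normalized = 0, ssim_loss = 0,
                tv = 0)
  for (s in batch) {
    fw <- unet_forward(model, s$hairy, cache = TRUE)
    lg <- composite_loss_grad(fw$pred, s$clean,
                              binarize_mask(s$mask, config$mask_threshold),
                              config$weights)
    if (!is.finite(lg$total))
      stop("non-finite training loss; aborting (components: ",
           paste(sprintf("%.3g", unlist(lg$components)), collapse = ", "),
           ")")
    g <- unet_backward(model, fw$cache, lg$grad)
    gacc <- if (is.null(gacc)) g else
      mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
             gacc, g, SIMPLIFY = FALSE)
    comp_acc <- comp_acc + unlist(lg$components)
  }
  nb <- length(batch)
  gacc <- lapply(gacc, function(l) list(W = l$W / nb, b = l$b / nb))
  comp <- structure(as.list(comp_acc / nb), class = "loss_components")
  upd <- adam_update(model$params, gacc, adam, t, config)
  model$params <- upd$params
  list(model = model, adam = upd$state, components = comp,
       total = total_loss(comp, config$weights))
}

#' Train the inpainting model
#'
#' Iterates [train_step()] over seeded-shuffled mini-batches drawn from the
#' training split only, recording the per-component loss history at every
#' step.
#'
#' @param model a `unet_model`.
#' @param data either a manifest data frame (rows with `split == "train"`
#'   are loaded from disk) or a list of `paired_sample`s.
#' @param config a [train_config()].
#' @return list with `model` (trained) and `history` (data frame with
#'   columns `iter`, `hair`, `non_hair`, `normalized`, `ssim_loss`, `tv`,
#'   `total`).
#' @export
train <- function(model, data, config = train_config()) {
  if (is.data.frame(data)) {
    rows <- if (!is.null(data$split)) data[data$split == "train", ] else data
    if (nrow(rows) == 0) stop("empty training split")
    samples <- lapply(seq_len(nrow(rows)),
                      function(i) load_paired_sample(rows[i, ]))
  } else {
    samples <- data
    if (length(samples) == 0) stop("no training samples")
  }
  n <- length(samples)
  history <- vector("list", config$iterations)
  adam <- adam_init(model$params)
  with_seed(config$seed, {
    order_pool <- integer(0)
    for (it in seq_len(config$iterations)) {
      while (length(order_pool) < config$batch_size)
        order_pool <- c(order_pool, sample(n))
      idx <- order_pool[seq_len(config$batch_size)]
      order_pool <- order_pool[-seq_len(config$batch_size)]
      st <- train_step(model, samples[idx], config, adam, t = it)
      model <- st$model
      adam <- st$adam
      history[[it]] <- data.frame(iter = it,
                                  hair = st$components$hair,
                                  non_hair = st$components$non_hair,
                                  normalized = st$components$normalized,
                                  ssim_loss = st$components$ssim_loss,
                                  tv = st$components$tv,
                                  total = st$total)
      if (config$checkpoint_every > 0 && !is.null(config$checkpoint_dir) &&
          it %% config$checkpoint_every == 0)
        save_model(model, file.path(config$checkpoint_dir,
                                    sprintf("ckpt_%06d", it)))
    }
  })
  list(model = model, history = do.call(rbind, history))
}

#' Write / read a loss history
#'
#' Plain CSV round-trip of the six-column per-iteration loss record.
#'
#' @param history history data frame from [train()].
#' @param path CSV path.
#' @return `write_loss_history` returns `path` invisibly;
#'   `read_loss_history` the data frame.
#' @export
write_loss_history <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_loss_history
#' @export
read_loss_history <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Plot the loss history
#'
#' Line chart of the five loss components and the total over training
#' iterations (log-scaled y axis).
#'
#' @param history history data frame from [train()].
#' @param ... passed to [graphics::matplot()].
#' @return `history`, invisibly.
#' @export
plot_loss_history <- function(history, ...) {
  comp <- history[, c("hair", "non_hair", "normalized", "ssim_loss", "tv")]
  graphics::matplot(history$iter, cbind(comp, total = history$total),
                    type = "l", lty = c(rep(2, 5), 1),
                    col = c(2:6, 1), lwd = c(rep(1, 5), 2),
                    xlab = "iteration", ylab = "loss", ...)
  graphics::legend("topright", c(names(comp), "total"), lty = c(rep(2, 5), 1),
                   col = c(2:6, 1), cex = 0.8, bty = "n")
  invisible(history)
}
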