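#' Apply the inpainting model to an image
#'
#' Convenience wrapper over [unet_forward()] for hairy images or
#' `paired_sample`s.
#'
#' @param model a `unet_model`.
#' @param x RGB array, `paired_sample`, or list of either.
#' @return the hair-removed RGB array (or list of arrays).
#' @export
remove_hair <- function(model, x) {
  if (inherits(x, "paired_sample")) return(unet_forward(model, x$hairy))
  if (is.list(x) && !is.array(x)) return(lapply(x, remove_hair, model = model))
  unet_forward(model, x)
}

#' Evaluate hair-removed images against clean ground truth
#'
#' For every test-split row of the manifest, reads the clean image and a
#' removed image `<removed_dir>/<sample_id>.png`, computes MSE, MAE, SSIM
#' and MS-SSIM, and optionally repeats the evaluation for the Dullrazor
#' baseline applied to the hairy images. Missing removed images are listed
#' in a warning and excluded.
#'
#' @param removed_dir directory of model outputs named by sample id.
#' @param manifest manifest data frame (rows with `split == "test"` are
#'   evaluated; all rows if there is no split column).
#' @param baseline `"dullrazor"` to add baseline columns, or `NULL`.
#' @return list with `per_sample` (one row per sample and method) and
#'   `summary` (mean and sd per metric per method).
#' @export
evaluate_pairs <- function(removed_dir, manifest, baseline = NULL) {
  rows <- if (!is.null(manifest$split))
    manifest[manifest$split == "test", ] else manifest
  if (nrow(rows) == 0) stop("no test rows to evaluate")
  missing <- character(0)
  recs <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    f <- file.path(removed_dir, paste0(r$sample_id, ".png"))
    if (!file.exists(f)) {
      missing <- c(missing, r$sample_id)
      next
    }
    clean <- read_image(r$clean_path)
    rec <- metrics_record(read_image(f), clean)
    recs[[length(recs) + 1]] <-
      data.frame(sample_id = r$sample_id, method = "model",
                 mse = rec$mse, mae = rec$mae, ssim = rec$ssim,
                 ms_ssim = rec$ms_ssim)
    if (identical(baseline, "dullrazor")) {
      dr <- dullrazor(read_image(r$hairy_path))
      rb <- metrics_record(dr$cleaned, clean)
      recs[[length(recs) + 1]] <-
        data.frame(sample_id = r$sample_id, method = "dullrazor",
                   mse = rb$mse, mae = rb$mae, ssim = rb$ssim,
                   ms_ssim = rb$ms_ssim)
    }
  }
  if (length(missing) > 0)
    warning("missing removed images excluded: ",
            paste(missing, collapse = ", "))
  per_sample <- do.call(rbind, recs)
  if (is.null(per_sample)) stop("no samples could be evaluated")
  summary <- do.call(rbind, lapply(split(per_sample, per_sample$method),
                                   function(d) {
    data.frame(method = d$method[1],
               mse_mean = mean(d$mse), mse_sd = sd_or_zero(d$mse),
               mae_mean = mean(d$mae), mae_sd = sd_or_zero(d$mae),
               ssim_mean = mean(d$ssim), ssim_sd = sd_or_zero(d$ssim),
               ms_ssim_mean = mean(d$ms_ssim),
               ms_ssim_sd = sd_or_zero(d$ms_ssim))
  }))
  rownames(summary) <- NULL
  list(per_sample = per_sample, summary = summary)
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

#' Hair-count robustness sweep
#'
#' For each hair count `k = 1..k_max`, masks with exactly `k` strands are
#' composited onto each clean image; the sweep records the mean and
#' standard deviation (over images) of `SSIM(hairy, clean)` before removal
#' and `SSIM(removed, clean)` after removal by the model.
#'
#' @param model a trained `unet_model` (an untrained model is allowed; the
#'   post-removal column then simply reflects it).
#' @param clean_images list of RGB arrays (e.g. 10 samples).
#' @param k_max largest hair count; default 20.
#' @param mask_config a [mask_gen_config()] (its `num_hairs_range` is
#'   overridden per `k`).
#' @param comp_config a [composite_config()].
#' @param seed integer seed.
#' @return data frame of class `sweep_result` with columns `k`, `pre_mean`,
#'   `pre_sd`, `post_mean`, `post_sd`.
#' @export
hair_count_sweep <- function(model, clean_images, k_max = 20L,
                             mask_config = NULL,
                             comp_config = composite_config(),
                             seed = 1L) {
  if (is.null(mask_config)) mask_config <- mask_gen_config()
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      k_max * length(clean_images)))
  out <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    cfg <- mask_config
    cfg$num_hairs_range <- c(k, k)
    pre <- post <- numeric(length(clean_images))
    for (ci in seq_along(clean_images)) {
      sd_i <- seeds[(k - 1L) * length(clean_images) + ci]
      mask <- generate_mask(cfg, seed = sd_i)
      pair <- composite(clean_images[[ci]], mask, comp_config, seed = sd_i)
      pre[ci] <- ssim(pair$hairy, pair$clean)
      if (!is.null(model))
        post[ci] <- ssim(remove_hair(model, pair), pair$clean)
    }
    out[[k]] <- data.frame(k = k, pre_mean = mean(pre),
                           pre_sd = sd_or_zero(pre),
                           post_mean = if (is.null(model)) NA else mean(post),
                           post_sd = if (is.null(model)) NA
                                     else sd_or_zero(post))
  }
  structure(do.call(rbind, out), class = c("sweep_result", "data.frame"))
}

#' Canned Dullrazor comparison experiment
#'
#' Builds a comparison set in the spirit of the 100-image protocol -
#' `n_clean` clean images with `masks_per` mask variants each, every mask
#' holding at least `min_hairs` strands - applies both the model and the
#' Dullrazor baseline, and returns per-sample metrics with a summary table.
#'
#' @param model a trained `unet_model`.
#' @param n_clean number of clean base images (synthetic skin fixtures).
#' @param masks_per mask variants per clean image.
#' @param min_hairs minimum strand count per mask; default 10.
#' @param canvas square canvas side; default 256.
#' @param seed integer seed.
#' @return list with `per_sample` and `summary` as in [evaluate_pairs()].
#' @export
compare_dullrazor <- function(model, n_clean = 10L, masks_per = 10L,
                              min_hairs = 10L, canvas = 256L, seed = 1L) {
  mask_cfg <- mask_gen_config(canvas_size = c(canvas, canvas),
                              num_hairs_range = c(min_hairs, 40L))
  skin_cfg <- synthetic_skin_config(canvas_size = c(canvas, canvas))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      n_clean * (masks_per + 1L)))
  tones <- c("light", "medium", "tan", "dark")
  recs <- list()
  for (ci in seq_len(n_clean)) {
    cfg_i <- skin_cfg
    cfg_i$skin_tone <- skin_tone_preset(tones[1L + (ci - 1L) %% 4L])
    clean <- generate_synthetic_skin(cfg_i, seed = seeds[ci])
    for (mi in seq_len(masks_per)) {
      sd_i <- seeds[n_clean + (ci - 1L) * masks_per + mi]
      pair <- composite(clean, generate_mask(mask_cfg, seed = sd_i),
                        seed = sd_i)
      sid <- sprintf("clean%02d_mask%02d", ci, mi)
      rm_ <- remove_hair(model, pair)
      rec <- metrics_record(rm_, clean)
      dr <- dullrazor(pair$hairy)
      rb <- metrics_record(dr$cleaned, clean)
      recs[[length(recs) + 1]] <-
        rbind(data.frame(sample_id = sid, method = "model", mse = rec$mse,
                         mae = rec$mae, ssim = rec$ssim,
                         ms_ssim = rec$ms_ssim),
              data.frame(sample_id = sid, method = "dullrazor",
                         mse = rb$mse, mae = rb$mae, ssim = rb$ssim,
                         ms_ssim = rb$ms_ssim))
    }
  }
  per_sample <- do.call(rbind, recs)
  summary <- do.call(rbind, lapply(split(per_sample, per_sample$method),
                                   function(d) {
    data.frame(method = d$method[1],
               mse_mean = mean(d$mse), mse_sd = sd_or_zero(d$mse),
               mae_mean = mean(d$mae), mae_sd = sd_or_zero(d$mae),
               ssim_mean = mean(d$ssim), ssim_sd = sd_or_zero(d$ssim),
               ms_ssim_mean = mean(d$ms_ssim),
               ms_ssim_sd = sd_or_zero(d$ms_ssim))
  }))
  rownames(summary) <- NULL
  list(per_sample = per_sample, summary = summary)
}
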