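#' Classify hair density from a strand count
#'
#' Density bins follow the benchmark design: 1-5 hairs are `low`, 6-20
#' `medium`, 21-40 `high`. Under a uniform 1-40 strand count these bins
#' carry 12.5%, 37.5% and 50% of the samples.
#'
#' @param n_hairs integer vector of strand counts in \[1, 40\].
#' @return character vector of `"low"`, `"medium"`, `"high"`.
#' @export
classify_density <- function(n_hairs) {
  n_hairs <- as.integer(n_hairs)
  if (any(is.na(n_hairs)) || any(n_hairs < 1L | n_hairs > 40L))
    stop("n_hairs must lie in [1, 40]")
  ifelse(n_hairs <= 5L, "low", ifelse(n_hairs <= 20L, "medium", "high"))
}

#' Assign train/test splits to a manifest
#'
#' The training set size is `ceiling(train_fraction * N)` (1064 samples at
#' 80% give 852 train / 212 test); assignment is by seeded shuffle. When a
#' `clean_id` column is present, all samples sharing a clean base image are
#' kept on the same side of the split (no leakage across variants of the
#' same image): shuffled clean-image groups are moved into the training set
#' until it holds at least the target number of samples.
#'
#' @param manifest data frame with one row per sample (needs `sample_id`;
#'   optionally `clean_id`).
#' @param train_fraction real in (0, 1); default 0.8.
#' @param seed integer seed for the shuffle.
#' @return the manifest with a `split` column of `"train"`/`"test"`.
#' @export
split_train_test <- function(manifest, train_fraction = 0.8, seed = 1L) {
  n <- nrow(manifest)
  if (is.null(n) || n == 0) stop("empty manifest")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (anyDuplicated(manifest$sample_id))
    stop("sample_ids must be unique")
  n_train <- as.integer(ceiling(train_fraction * n))
  groups <- if (!is.null(manifest$clean_id)) manifest$clean_id
            else manifest$sample_id
  with_seed(seed, {
    ids <- sample(unique(groups))
    sizes <- as.integer(table(groups)[ids])
    k <- which(cumsum(sizes) >= n_train)[1]
    train_groups <- ids[seq_len(k)]
    manifest$split <- ifelse(groups %in% train_groups, "train", "test")
  })
  manifest
}

#' Build a paired synthetic-hair dataset
#'
#' For each sample: obtain a clean lesion image (from a directory of PNGs,
#' cycled when `n_samples` exceeds the number of files, or from the
#' synthetic-skin generator), generate a hair mask, composite the hairy
#' image, and write `clean/`, `hairy/`, `masks/` PNGs plus JSON mask
#' metadata. Returns the manifest with density classes and the train/test
#' split, and writes it as `manifest.csv` with a `config.json` snapshot.
#'
#' @param out_dir output directory (created if missing).
#' @param n_samples number of paired samples to generate.
#' @param clean_source `NULL` to use the synthetic-skin generator, or a
#'   directory of clean PNG images (resized to the mask canvas with
#'   bilinear interpolation).
#' @param skin_config a [synthetic_skin_config()] for generated clean images
#'   (skin-tone presets are cycled across samples).
#' @param mask_config a [mask_gen_config()].
#' @param comp_config a [composite_config()].
#' @param train_fraction passed to [split_train_test()].
#' @param seed master seed; all per-sample seeds derive from it.
#' @return the manifest data frame.
#' @export
build_dataset <- function(out_dir, n_samples,
                          clean_source = NULL,
                          skin_config = NULL,
                          mask_config = NULL,
                          comp_config = composite_config(),
                          train_fraction = 0.8,
                          seed = 1L) {
  stopifnot(n_samples >= 1)
  if (is.null(mask_config)) mask_config <- mask_gen_config()
  if (is.null(skin_config))
    skin_config <- synthetic_skin_config(canvas_size = mask_config$canvas_size)
  for (d in file.path(out_dir, c("clean", "hairy", "masks")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)

  clean_files <- NULL
  if (!is.null(clean_source)) {
    clean_files <- sort(list.files(clean_source, pattern = "\\.png$",
                                   full.names = TRUE))
    if (length(clean_files) == 0)
      stop("no PNG images found in ", clean_source)
  }

  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_samples))
  tones <- c("light", "medium", "tan", "dark")
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sid <- sprintf("sample_%05d", i)
    if (is.null(clean_files)) {
      cfg_i <- skin_config
      cfg_i$skin_tone <- skin_tone_preset(tones[1L + (i - 1L) %% 4L])
      clean <- generate_synthetic_skin(cfg_i, seed = seeds[i])
      clean_id <- sid
    } else {
      f <- clean_files[1L + (i - 1L) %% length(clean_files)]
      clean_id <- sub("\\.png$", "", basename(f))
      clean <- tryCatch(read_image(f), error = function(e) {
        warning("skipping unreadable clean image: ", f)
        NULL
      })
      if (is.null(clean)) next
      if (!all(dim(clean)[1:2] == mask_config$canvas_size)) {
        rs <- array(0, c(mask_config$canvas_size, 3))
        for (ch in 1:3)
          rs[, , ch] <- resize_bilinear(clean[, , ch],
                                        mask_config$canvas_size[1],
                                        mask_config$canvas_size[2])
        clean <- clamp(rs)
      }
    }
    mask <- generate_mask(mask_config, seed = seeds[i])
    pair <- composite(clean, mask, comp_config, seed = seeds[i])
    paths <- file.path(out_dir, c("clean", "hairy", "masks"),
                       paste0(sid, ".png"))
    write_image(pair$clean, paths[1])
    write_image(pair$hairy, paths[2])
    write_mask(mask, paths[3])
    rows[[i]] <- data.frame(sample_id = sid, clean_id = clean_id,
                            clean_path = paths[1], hairy_path = paths[2],
                            mask_path = paths[3],
                            n_hairs = mask$strand_count,
                            density_class =
                              classify_density(mask$strand_count),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (is.null(manifest) || nrow(manifest) == 0)
    stop("no samples could be built")
  manifest <- split_train_test(manifest, train_fraction, seed = seed)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  snapshot <- list(n_samples = n_samples, seed = seed,
                   train_fraction = train_fraction,
                   mask_config = unclass(mask_config),
                   composite_config = unclass(comp_config),
                   skin_config = if (is.null(clean_files))
                     unclass(skin_config) else NULL,
                   clean_source = clean_source)
  jsonlite::write_json(snapshot, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}

#' Write / read a dataset manifest
#'
#' The manifest is a plain one-header-row UTF-8 CSV; reading it back yields
#' an identical data frame.
#'
#' @param manifest manifest data frame.
#' @param path CSV file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Load one paired sample from manifest paths
#'
#' @param row one manifest row (data frame with `clean_path`, `hairy_path`,
#'   `mask_path`).
#' @return a `paired_sample`.
#' @export
load_paired_sample <- function(row) {
  mask <- read_mask(row$mask_path)
  m <- if (inherits(mask, "hair_mask")) mask$values else mask
  structure(list(clean = read_image(row$clean_path),
                 hairy = read_image(row$hairy_path),
                 mask = m,
                 meta = list(sample_id = row$sample_id,
                             n_hairs = row$n_hairs %||% NA_integer_)),
            class = "paired_sample")
}
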