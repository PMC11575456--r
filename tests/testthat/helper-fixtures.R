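# Shared small fixtures, generated in code at test time.

tiny_mask_config <- function(canvas = 64L, working = 256L, ...) {
  mask_gen_config(canvas_size = c(canvas, canvas), working_size = working,
                  ...)
}

tiny_skin <- function(canvas = 64L, seed = 7L, ...) {
  generate_synthetic_skin(
    synthetic_skin_config(canvas_size = c(canvas, canvas), ...), seed = seed)
}

tiny_pair <- function(canvas = 64L, seed = 7L, n_hairs = NULL) {
  cfg <- tiny_mask_config(canvas)
  if (!is.null(n_hairs)) cfg$num_hairs_range <- c(n_hairs, n_hairs)
  clean <- tiny_skin(canvas, seed)
  composite(clean, generate_mask(cfg, seed = seed + 1), seed = seed + 2)
}

rand_img <- function(h, w = h, ch = 3L) {
  array(runif(h * w * ch), c(h, w, ch))
}

# a correlated pair of smooth-ish random images (plain iid noise makes SSIM
# nearly 0 everywhere, a weak test case)
rand_img_pair <- function(h, w = h, ch = 3L, noise = 0.1) {
  base <- rand_img(h, w, ch)
  for (c_ in seq_len(ch)) {
    k <- matrix(1 / 9, 3, 3)
    s <- base[, , c_]
    sm <- s
    sm[2:(h - 1), 2:(w - 1)] <-
      (s[1:(h - 2), 1:(w - 2)] + s[1:(h - 2), 2:(w - 1)] + s[1:(h - 2), 3:w] +
       s[2:(h - 1), 1:(w - 2)] + s[2:(h - 1), 2:(w - 1)] + s[2:(h - 1), 3:w] +
       s[3:h, 1:(w - 2)] + s[3:h, 2:(w - 1)] + s[3:h, 3:w]) / 9
    base[, , c_] <- sm
  }
  list(a = base,
       b = pmin(pmax(base + array(rnorm(h * w * ch, 0, noise),
                                  c(h, w, ch)), 0), 1))
}
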