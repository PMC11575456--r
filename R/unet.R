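#' U-Net configuration
#'
#' A symmetric encoder-decoder with skip connections. Each encoder level
#' applies two 3x3 convolutions with rectified-linear activations followed by
#' 2x2 max pooling (except the deepest level); each decoder level upsamples
#' with a 2x2 transposed convolution, concatenates the matching encoder
#' feature map, and applies two 3x3 convolutions. A final 1x1 convolution
#' with a sigmoid maps features back to a 3-channel image in \[0, 1\].
#' Channel width doubles per level starting from `base_channels`.
#'
#' @param depth number of encoder levels (`depth - 1` skip connections);
#'   input height/width must be divisible by `2^(depth - 1)`.
#' @param base_channels feature channels at the first level.
#' @param input_size `(height, width, channels)`; default `c(256, 256, 3)`.
#' @param norm `"instance"` (default) applies per-channel instance
#'   normalization with learnable scale/shift after every 3x3 convolution
#'   (before the rectifier), which keeps the optimization well conditioned
#'   at small learning rates; `"none"` disables it.
#' @param init_seed seed for the parameter initialization.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 16L,
                        input_size = c(256L, 256L, 3L),
                        norm = c("instance", "none"), init_seed = 1L) {
  depth <- as.integer(depth)
  norm <- match.arg(norm)
  stopifnot(depth >= 1, base_channels >= 1, length(input_size) == 3)
  div <- 2L^(depth - 1L)
  if (input_size[1] %% div != 0 || input_size[2] %% div != 0)
    stop("input height and width must be divisible by 2^(depth - 1)")
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 kernel_size = 3L, output_kernel = 1L,
                 input_size = as.integer(input_size), norm = norm,
                 init_seed = as.integer(init_seed)),
            class = "unet_config")
}

# instance normalization: per-channel spatial standardisation with
# learnable scale (W) and shift (b)
new_instnorm <- function(cout) {
  list(W = rep(1, cout), b = numeric(cout), cout = cout, norm = TRUE)
}

instnorm_fw <- function(z, gamma, beta, eps = 1e-5) {
  out <- z
  zhat <- z
  inv_sd <- numeric(dim(z)[3])
  for (c_ in seq_len(dim(z)[3])) {
    s <- z[, , c_]
    mu <- mean(s)
    v <- mean(s * s) - mu * mu
    inv_sd[c_] <- 1 / sqrt(v + eps)
    zh <- (s - mu) * inv_sd[c_]
    zhat[, , c_] <- zh
    out[, , c_] <- gamma[c_] * zh + beta[c_]
  }
  list(out = out, zhat = zhat, inv_sd = inv_sd)
}

instnorm_bw <- function(cache, gamma, gout) {
  gz <- gout
  ng <- length(gamma)
  dgamma <- numeric(ng)
  dbeta <- numeric(ng)
  for (c_ in seq_len(ng)) {
    go <- gout[, , c_]
    zh <- cache$zhat[, , c_]
    dgamma[c_] <- sum(go * zh)
    dbeta[c_] <- sum(go)
    dzh <- go * gamma[c_]
    n <- length(go)
    gz[, , c_] <- (cache$inv_sd[c_] / n) *
      (n * dzh - sum(dzh) - zh * sum(dzh * zh))
  }
  list(gz = gz, gW = dgamma, gb = dbeta)
}

# conv parameter container: W is (k*k*Cin) x Cout (He-initialized), b zeros
new_conv <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  list(W = matrix(rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

# transposed-conv parameters: W is Cin x (4 * Cout), column q = co*4+dj*2+di
new_upconv <- function(cin, cout) {
  sd <- sqrt(2 / (4 * cin))
  list(W = matrix(rnorm(cin * 4 * cout, 0, sd), cin, 4 * cout),
       b = numeric(cout), cin = cin, cout = cout)
}

#' Initialize a U-Net model
#'
#' Parameters are drawn from seeded He-scaled normals, so the same
#' `init_seed` yields bit-identical models.
#'
#' @param config a [unet_config()].
#' @return an object of class `unet_model` holding the parameter list and
#'   the config.
#' @export
unet_init <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  d <- config$depth
  ch <- config$base_channels * 2L^(seq_len(d) - 1L)
  use_norm <- identical(config$norm, "instance")
  params <- with_seed(config$init_seed, {
    p <- list()
    cin <- config$input_size[3]
    for (l in seq_len(d)) {
      p[[sprintf("enc%d_conv1", l)]] <- new_conv(3L, cin, ch[l])
      if (use_norm) p[[sprintf("enc%d_in1", l)]] <- new_instnorm(ch[l])
      p[[sprintf("enc%d_conv2", l)]] <- new_conv(3L, ch[l], ch[l])
      if (use_norm) p[[sprintf("enc%d_in2", l)]] <- new_instnorm(ch[l])
      cin <- ch[l]
    }
    for (l in rev(seq_len(d - 1L))) {
      p[[sprintf("up%d", l)]] <- new_upconv(ch[l + 1L], ch[l])
      p[[sprintf("dec%d_conv1", l)]] <- new_conv(3L, 2L * ch[l], ch[l])
      if (use_norm) p[[sprintf("dec%d_in1", l)]] <- new_instnorm(ch[l])
      p[[sprintf("dec%d_conv2", l)]] <- new_conv(3L, ch[l], ch[l])
      if (use_norm) p[[sprintf("dec%d_in2", l)]] <- new_instnorm(ch[l])
    }
    p[["out"]] <- new_conv(1L, ch[1], 3L)
    p
  })
  structure(list(params = params, config = config), class = "unet_model")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

conv_fw <- function(x, layer, pad) {
  cpp_conv2d_fw(x, layer$W, layer$b, layer$k, pad)
}

# two 3x3 convolutions with optional instance norm, ReLU after each
block_fw <- function(a_in, conv1, in1, conv2, in2) {
  z1 <- conv_fw(a_in, conv1, 1L)
  i1 <- NULL
  pre1 <- z1
  if (!is.null(in1)) {
    i1 <- instnorm_fw(z1, in1$W, in1$b)
    pre1 <- i1$out
  }
  a1 <- relu(pre1)
  z2 <- conv_fw(a1, conv2, 1L)
  i2 <- NULL
  pre2 <- z2
  if (!is.null(in2)) {
    i2 <- instnorm_fw(z2, in2$W, in2$b)
    pre2 <- i2$out
  }
  list(out = relu(pre2),
       cache = list(a_in = a_in, pre1 = pre1, a1 = a1, pre2 = pre2,
                    i1 = i1, i2 = i2))
}

block_bw <- function(gout, cache, conv1, in1, conv2, in2) {
  gpre2 <- gout * (cache$pre2 > 0)
  g_in2 <- NULL
  gz2 <- gpre2
  if (!is.null(in2)) {
    nb <- instnorm_bw(cache$i2, in2$W, gpre2)
    gz2 <- nb$gz
    g_in2 <- list(W = nb$gW, b = nb$gb)
  }
  bw2 <- cpp_conv2d_bw(cache$a1, conv2$W, gz2, 3L, 1L)
  gpre1 <- bw2$gx * (cache$pre1 > 0)
  g_in1 <- NULL
  gz1 <- gpre1
  if (!is.null(in1)) {
    nb <- instnorm_bw(cache$i1, in1$W, gpre1)
    gz1 <- nb$gz
    g_in1 <- list(W = nb$gW, b = nb$gb)
  }
  bw1 <- cpp_conv2d_bw(cache$a_in, conv1$W, gz1, 3L, 1L)
  list(gin = bw1$gx,
       g_conv1 = list(W = bw1$gW, b = as.numeric(bw1$gb)), g_in1 = g_in1,
       g_conv2 = list(W = bw2$gW, b = as.numeric(bw2$gb)), g_in2 = g_in2)
}

#' Forward pass of the U-Net
#'
#' @param model a [unet_init()] model.
#' @param x input array `H x W x C` (or a list of such arrays).
#' @param cache keep intermediate activations for [unet_backward()].
#' @return the predicted image array in \[0, 1\] (same spatial size, 3
#'   channels); with `cache = TRUE`, a list `(pred, cache)`. Lists of inputs
#'   give lists of predictions.
#' @export
unet_forward <- function(model, x, cache = FALSE) {
  if (is.list(x) && !is.array(x))
    return(lapply(x, function(xi) unet_forward(model, xi, cache = cache)))
  stopifnot(inherits(model, "unet_model"), length(dim(x)) == 3)
  cfg <- model$config
  if (dim(x)[3] != cfg$input_size[3])
    stop("input channel count does not match the model config")
  div <- 2L^(cfg$depth - 1L)
  if (dim(x)[1] %% div != 0 || dim(x)[2] %% div != 0)
    stop("input size not divisible by 2^(depth - 1)")
  p <- model$params
  d <- cfg$depth
  cc <- list(x = x, z = list(), e = list(), pool = list(), u = list())

  a <- x
  for (l in seq_len(d)) {
    bl <- block_fw(a, p[[sprintf("enc%d_conv1", l)]],
                   p[[sprintf("enc%d_in1", l)]],
                   p[[sprintf("enc%d_conv2", l)]],
                   p[[sprintf("enc%d_in2", l)]])
    cc$z[[l]] <- bl$cache
    cc$e[[l]] <- bl$out
    if (l < d) {
      mp <- cpp_maxpool2_fw(bl$out)
      cc$pool[[l]] <- mp$idx
      a <- mp$y
    }
  }

  dcur <- cc$e[[d]]
  for (l in rev(seq_len(d - 1L))) {
    up <- p[[sprintf("up%d", l)]]
    zu <- cpp_upconv2_fw(dcur, up$W, up$b)
    au <- relu(zu)
    ccat <- abind3(au, cc$e[[l]])
    bl <- block_fw(ccat, p[[sprintf("dec%d_conv1", l)]],
                   p[[sprintf("dec%d_in1", l)]],
                   p[[sprintf("dec%d_conv2", l)]],
                   p[[sprintf("dec%d_in2", l)]])
    cc$u[[l]] <- list(d_in = dcur, zu = zu, ccat_width = dim(au)[3],
                      block = bl$cache)
    dcur <- bl$out
  }

  zout <- conv_fw(dcur, p[["out"]], 0L)
  pred <- 1 / (1 + exp(-zout))
  if (!cache) return(pred)
  cc$d_final <- dcur
  cc$pred <- pred
  list(pred = pred, cache = cc)
}

abind3 <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

#' Backward pass: parameter gradients from an output gradient
#'
#' Backpropagates `gpred` (the gradient of a scalar loss with respect to the
#' sigmoid output) through the network and returns gradients with the same
#' structure as `model$params`.
#'
#' @param model a `unet_model`.
#' @param cache the cache returned by `unet_forward(..., cache = TRUE)`.
#' @param gpred array of the same shape as the prediction.
#' @return named list of gradients (`W`, `b` per layer).
#' @export
unet_backward <- function(model, cache, gpred) {
  p <- model$params
  d <- model$config$depth
  grads <- list()

  gz <- gpred * cache$pred * (1 - cache$pred)  # sigmoid
  bw <- cpp_conv2d_bw(cache$d_final, p[["out"]]$W, gz, 1L, 0L)
  grads[["out"]] <- list(W = bw$gW, b = as.numeric(bw$gb))
  gd <- bw$gx

  ge_extra <- vector("list", d)  # gradients flowing into encoder maps e_l
  for (l in seq_len(d - 1L)) {
    u <- cache$u[[l]]
    bb <- block_bw(gd, u$block,
                   p[[sprintf("dec%d_conv1", l)]],
                   p[[sprintf("dec%d_in1", l)]],
                   p[[sprintf("dec%d_conv2", l)]],
                   p[[sprintf("dec%d_in2", l)]])
    grads[[sprintf("dec%d_conv1", l)]] <- bb$g_conv1
    grads[[sprintf("dec%d_conv2", l)]] <- bb$g_conv2
    if (!is.null(bb$g_in1)) grads[[sprintf("dec%d_in1", l)]] <- bb$g_in1
    if (!is.null(bb$g_in2)) grads[[sprintf("dec%d_in2", l)]] <- bb$g_in2
    ca <- u$ccat_width
    gau <- bb$gin[, , seq_len(ca), drop = FALSE]
    ge_extra[[l]] <- bb$gin[, , ca + seq_len(dim(bb$gin)[3] - ca),
                            drop = FALSE]
    gzu <- gau * (u$zu > 0)
    upn <- sprintf("up%d", l)
    bwu <- cpp_upconv2_bw(u$d_in, p[[upn]]$W, gzu)
    grads[[upn]] <- list(W = bwu$gW, b = as.numeric(bwu$gb))
    gd <- bwu$gx  # gradient w.r.t. the deeper decoder output / encoder e_d
  }

  # encoder, deepest level first; gd currently targets e_d
  ge <- gd
  for (l in rev(seq_len(d))) {
    if (l < d) {
      ge <- cpp_maxpool2_bw(cache$pool[[l]], ge)
      ge <- ge + ge_extra[[l]]
    }
    bb <- block_bw(ge, cache$z[[l]],
                   p[[sprintf("enc%d_conv1", l)]],
                   p[[sprintf("enc%d_in1", l)]],
                   p[[sprintf("enc%d_conv2", l)]],
                   p[[sprintf("enc%d_in2", l)]])
    grads[[sprintf("enc%d_conv1", l)]] <- bb$g_conv1
    grads[[sprintf("enc%d_conv2", l)]] <- bb$g_conv2
    if (!is.null(bb$g_in1)) grads[[sprintf("enc%d_in1", l)]] <- bb$g_in1
    if (!is.null(bb$g_in2)) grads[[sprintf("enc%d_in2", l)]] <- bb$g_in2
    ge <- bb$gin
  }
  grads[names(p)]
}

# flatten parameters (or same-shaped gradients) to one numeric vector
flatten_params <- function(params) {
  unlist(lapply(params, function(l) c(as.numeric(l$W), as.numeric(l$b))),
         use.names = FALSE)
}

unflatten_params <- function(flat, template) {
  pos <- 1L
  for (nm in names(template)) {
    nw <- length(template[[nm]]$W)
    template[[nm]]$W[] <- flat[pos:(pos + nw - 1L)]
    pos <- pos + nw
    nb <- length(template[[nm]]$b)
    template[[nm]]$b[] <- flat[pos:(pos + nb - 1L)]
    pos <- pos + nb
  }
  template
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory with `config.json` (architecture, format
#' version) and `params.bin` (flattened parameters as little-endian
#' doubles in canonical layer order).
#'
#' @param model a `unet_model`.
#' @param path checkpoint directory.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  cfg$format_version <- 1L
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "params.bin"), "wb")
  on.exit(close(con))
  writeBin(flatten_params(model$params), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfg <- jsonlite::read_json(file.path(path, "config.json"),
                             simplifyVector = TRUE)
  config <- unet_config(depth = cfg$depth, base_channels = cfg$base_channels,
                        input_size = cfg$input_size,
                        norm = cfg$norm %||% "instance",
                        init_seed = cfg$init_seed)
  model <- unet_init(config)
  n <- length(flatten_params(model$params))
  con <- file(file.path(path, "params.bin"), "rb")
  on.exit(close(con))
  flat <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(flat) != n) stop("checkpoint parameter count mismatch")
  model$params <- unflatten_params(flat, model$params)
  model
}

#' @export
print.unet_model <- function(x, ...) {
  np <- length(flatten_params(x$params))
  cat(sprintf("<unet_model> depth %d, base %d channels, %s parameters\n",
              x$config$depth, x$config$base_channels,
              format(np, big.mark = ",")))
  invisible(x)
}
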