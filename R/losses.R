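#' Loss weights for the composite objective
#'
#' The composite training objective is
#' `L_total = l1*L_hair + l2*L_non_hair + l3*L_normalized + l4*L_ssim +
#' l5*L_tv`. The tuned default `(2.5, 3.5, 0.3, 1, 0.5)` prioritises the
#' hair and non-hair reconstruction terms and keeps the normalised hair
#' error, SSIM and total-variation terms as milder regularisers.
#'
#' @param lambda1,lambda2,lambda3,lambda4,lambda5 non-negative weights for
#'   the hair, non-hair, normalised, SSIM and total-variation components.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 2.5, lambda2 = 3.5, lambda3 = 0.3,
                         lambda4 = 1, lambda5 = 0.5) {
  w <- c(lambda1, lambda2, lambda3, lambda4, lambda5)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and non-negative")
  structure(as.numeric(w), class = "loss_weights",
            names = paste0("lambda", 1:5))
}

#' Named loss-weight presets
#'
#' `"tuned"` is `(2.5, 3.5, 0.3, 1, 0.5)`, `"uniform"` is all ones, and
#' `"initial"` is `(0.5, 0.5, 0.2, 0.2, 0.2)` - the three configurations
#' compared when calibrating the objective.
#'
#' @param name one of `"tuned"`, `"uniform"`, `"initial"`.
#' @return a [loss_weights()] vector.
#' @export
preset_weights <- function(name = c("tuned", "uniform", "initial")) {
  name <- match.arg(name)
  switch(name,
         tuned   = loss_weights(2.5, 3.5, 0.3, 1, 0.5),
         uniform = loss_weights(1, 1, 1, 1, 1),
         initial = loss_weights(0.5, 0.5, 0.2, 0.2, 0.2))
}

check_shapes <- function(pred, target, hair = NULL) {
  if (!all(dim(pred) == dim(target))) stop("image shapes differ")
  if (!is.null(hair) && !all(dim(hair) == dim(pred)[1:2]))
    stop("hair mask shape differs from the images")
}

#' Hair-region reconstruction loss
#'
#' Mean squared difference over hair pixels (all channels); 0 when the hair
#' set is empty.
#'
#' @param pred,target RGB arrays `H x W x 3` of the same shape.
#' @param hair logical matrix from [binarize_mask()].
#' @return non-negative scalar.
#' @export
loss_hair <- function(pred, target, hair) {
  check_shapes(pred, target, hair)
  n <- sum(hair)
  if (n == 0) return(0)
  d2 <- (pred - target)^2
  sum(apply(d2, 3, function(ch) sum(ch[hair]))) / (n * dim(pred)[3])
}

#' Non-hair-region reconstruction loss
#'
#' Mean squared difference over the complement of the hair set; 0 when the
#' complement is empty.
#'
#' @inheritParams loss_hair
#' @return non-negative scalar.
#' @export
loss_non_hair <- function(pred, target, hair) {
  check_shapes(pred, target, hair)
  loss_hair(pred, target, !hair)
}

#' Image-normalised hair loss
#'
#' Sum of squared differences over hair pixels divided by the total pixel
#' count of the image (times channels), i.e. the hair error expressed
#' relative to the whole image: it equals `loss_hair * |hair| / |all|`.
#'
#' @inheritParams loss_hair
#' @return non-negative scalar.
#' @export
loss_normalized <- function(pred, target, hair) {
  check_shapes(pred, target, hair)
  d2 <- (pred - target)^2
  sum(apply(d2, 3, function(ch) sum(ch[hair]))) / length(pred)
}

#' SSIM loss
#'
#' `1 - ssim(pred, target)`; see [ssim()] for the windowing constants.
#'
#' @inheritParams loss_hair
#' @return scalar in \[0, 2\].
#' @export
loss_ssim <- function(pred, target) {
  check_shapes(pred, target)
  1 - ssim(pred, target)
}

#' Anisotropic total-variation loss
#'
#' Mean absolute difference between horizontally and vertically adjacent
#' pixels, averaged over channels. Absolute (rather than squared)
#' differences keep the penalty edge-preserving.
#'
#' @param pred RGB array (or matrix).
#' @return non-negative scalar.
#' @export
loss_tv <- function(pred) {
  if (is.matrix(pred)) pred <- array(pred, c(dim(pred), 1L))
  h <- dim(pred)[1]; w <- dim(pred)[2]
  npairs <- h * (w - 1) + (h - 1) * w
  vals <- vapply(seq_len(dim(pred)[3]), function(ch) {
    s <- pred[, , ch]
    (sum(abs(s[, -1] - s[, -w])) + sum(abs(s[-1, ] - s[-h, ]))) / npairs
  }, 0)
  mean(vals)
}

#' Compute all five loss components
#'
#' @inheritParams loss_hair
#' @return a named list of class `loss_components` with fields `hair`,
#'   `non_hair`, `normalized`, `ssim_loss`, `tv`.
#' @export
loss_components <- function(pred, target, hair) {
  structure(list(hair = loss_hair(pred, target, hair),
                 non_hair = loss_non_hair(pred, target, hair),
                 normalized = loss_normalized(pred, target, hair),
                 ssim_loss = loss_ssim(pred, target),
                 tv = loss_tv(pred)),
            class = "loss_components")
}

#' Weighted composite loss
#'
#' @param components a [loss_components()] list.
#' @param weights a [loss_weights()] vector.
#' @return the weighted sum
#'   `l1*hair + l2*non_hair + l3*normalized + l4*ssim_loss + l5*tv`.
#' @export
total_loss <- function(components, weights = loss_weights()) {
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights,
                                                             as.list(weights))
  v <- c(components$hair, components$non_hair, components$normalized,
         components$ssim_loss, components$tv)
  if (any(!is.finite(v))) stop("non-finite loss component")
  sum(as.numeric(weights) * v)
}

# components, total and the gradient of the total loss w.r.t. pred --
# everything train_step needs from one sample
composite_loss_grad <- function(pred, target, hair,
                                weights = loss_weights()) {
  check_shapes(pred, target, hair)
  w <- as.numeric(weights)
  nch <- dim(pred)[3]
  h <- dim(pred)[1]; wd <- dim(pred)[2]
  diff <- pred - target
  nhair <- sum(hair); nnon <- length(hair) - nhair

  hair3 <- array(hair, dim(pred))
  d2 <- diff^2
  sum_hair <- sum(d2[hair3])
  sum_non <- sum(d2) - sum_hair

  l_hair <- if (nhair > 0) sum_hair / (nhair * nch) else 0
  l_non <- if (nnon > 0) sum_non / (nnon * nch) else 0
  l_norm <- sum_hair / length(pred)

  sg <- ssim_with_grad(pred, target)
  l_ssim <- 1 - sg$value

  # tv value and gradient
  npairs <- h * (wd - 1) + (h - 1) * wd
  l_tv <- 0
  g_tv <- array(0, dim(pred))
  for (ch in seq_len(nch)) {
    s <- pred[, , ch]
    dh <- s[, -1] - s[, -wd]
    dv <- s[-1, ] - s[-h, ]
    l_tv <- l_tv + (sum(abs(dh)) + sum(abs(dv))) / npairs
    g <- matrix(0, h, wd)
    sh <- sign(dh); sv <- sign(dv)
    g[, -1] <- g[, -1] + sh
    g[, -wd] <- g[, -wd] - sh
    g[-1, ] <- g[-1, ] + sv
    g[-h, ] <- g[-h, ] - sv
    g_tv[, , ch] <- g / (npairs * nch)
  }
  l_tv <- l_tv / nch

  grad <- array(0, dim(pred))
  if (nhair > 0)
    grad <- grad + w[1] * 2 * diff * hair3 / (nhair * nch)
  if (nnon > 0)
    grad <- grad + w[2] * 2 * diff * (!hair3) / (nnon * nch)
  grad <- grad + w[3] * 2 * diff * hair3 / length(pred)
  grad <- grad - w[4] * sg$grad
  grad <- grad + w[5] * g_tv

  comps <- structure(list(hair = l_hair, non_hair = l_non,
                          normalized = l_norm, ssim_loss = l_ssim,
                          tv = l_tv),
                     class = "loss_components")
  list(components = comps, total = total_loss(comps, weights), grad = grad)
}

#' @export
print.loss_components <- function(x, ...) {
  cat(sprintf(
    "<loss_components> hair %.4g | non_hair %.4g | normalized %.4g | ssim %.4g | tv %.4g\n",
    x$hair, x$non_hair, x$normalized, x$ssim_loss, x$tv))
  invisible(x)
}
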