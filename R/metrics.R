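#' Mean squared / absolute error between two images
#'
#' @param a,b images of identical shape with values in \[0, 1\].
#' @return non-negative scalar.
#' @export
mse <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  mean((a - b)^2)
}

#' @rdname mse
#' @export
mae <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  mean(abs(a - b))
}

#' Full quality record for one image pair
#'
#' @param a,b images of identical shape.
#' @param ms_scales number of MS-SSIM scales; by default the largest count
#'   (up to 5) the image size supports.
#' @return list of class `metrics_record` with `mse`, `mae`, `ssim`,
#'   `ms_ssim`.
#' @export
metrics_record <- function(a, b, ms_scales = NULL) {
  if (is.null(ms_scales))
    ms_scales <- max(1L, min(5L, 1L + floor(log2(min(dim(a)[1:2]) / 11))))
  structure(list(mse = mse(a, b), mae = mae(a, b), ssim = ssim(a, b),
                 ms_ssim = ms_ssim(a, b, scales = ms_scales)),
            class = "metrics_record")
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2pr / (p + r)`, defined as 0 when `p + r == 0`.
#'
#' @param precision,recall values in \[0, 1\].
#' @return scalar in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Near-mask precision / recall / F1 of hair removal
#'
#' A pixel counts as "predicted hair" when the removal changed it:
#' `max_channel |removed - hairy| >= change_threshold`. Ground truth is the
#' binarized mask. Precision is computed with a spatial tolerance: a
#' predicted pixel is a true positive when it falls inside the ground truth
#' dilated by `dilation_radius` (a disc), so edits hugging the mask border
#' are not penalised; recall is `|predicted intersect truth| / |truth|`.
#'
#' @param removed,hairy RGB arrays of the same shape.
#' @param mask a [hair_mask] or numeric matrix.
#' @param dilation_radius tolerance radius in pixels; default 5.
#' @param change_threshold minimum per-channel change; default 0.02.
#' @param mask_threshold binarization threshold for the ground truth.
#' @return list of class `prf_record` with `precision`, `recall`, `f1`,
#'   `dilation_radius` and `empty_truth` (TRUE when the mask has no hair
#'   pixels, in which case recall is reported as 0).
#' @export
prf_near_mask <- function(removed, hairy, mask, dilation_radius = 5L,
                          change_threshold = 0.02, mask_threshold = 0.1) {
  if (!all(dim(removed) == dim(hairy))) stop("image shapes differ")
  truth <- binarize_mask(mask, mask_threshold)
  if (!all(dim(truth) == dim(removed)[1:2]))
    stop("mask shape differs from the images")
  delta <- abs(removed - hairy)
  changed <- apply(delta, c(1, 2), max) >= change_threshold
  region <- dilate_mask(truth, dilation_radius)
  empty <- !any(truth)
  npred <- sum(changed)
  precision <- if (npred > 0) sum(changed & region) / npred else 0
  recall <- if (empty) 0 else sum(changed & truth) / sum(truth)
  structure(list(precision = precision, recall = recall,
                 f1 = f1_score(precision, recall),
                 dilation_radius = as.integer(dilation_radius),
                 empty_truth = empty),
            class = "prf_record")
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0.5
}
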