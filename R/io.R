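#' Read an RGB image from a PNG file
#'
#' Images are returned as `H x W x 3` numeric arrays with values in \[0, 1\].
#' Grayscale files are replicated across channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path path to a PNG file.
#' @return numeric array `H x W x 3`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  x <- png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), dim = c(dim(x)[1:2], 3L))
  x
}

#' Write an RGB image to a PNG file
#'
#' @param img numeric array `H x W x 3` in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp(img), path)
  invisible(path)
}

#' Write a hair mask as an 8-bit single-channel PNG
#'
#' Pixel values are `round(255 * v)`. When `meta = TRUE` a JSON sidecar with
#' the strand specifications is written next to the image.
#'
#' @param mask a [hair_mask] object or a numeric matrix in \[0, 1\].
#' @param path output path (`.png`).
#' @param meta write a `.json` sidecar with generation metadata.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, meta = inherits(mask, "hair_mask")) {
  v <- if (inherits(mask, "hair_mask")) mask$values else mask
  png::writePNG(clamp(v), path)
  if (meta && inherits(mask, "hair_mask")) {
    side <- sub("\\.png$", ".json", path)
    jsonlite::write_json(mask_metadata(mask), side, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a hair mask from a single-channel PNG
#'
#' @param path path to a PNG written by [write_mask()].
#' @return a [hair_mask] when a JSON sidecar with strand metadata is present,
#'   otherwise a plain numeric matrix in \[0, 1\].
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (!is.matrix(x)) x <- x[, , 1]
  side <- sub("\\.png$", ".json", path)
  if (!file.exists(side)) return(x)
  m <- jsonlite::read_json(side, simplifyVector = TRUE)
  st <- m$strands
  specs <- lapply(seq_len(length(st$thickness)), function(i) {
    cp <- rbind(c(st$p0r[i], st$p0c[i]), c(st$p1r[i], st$p1c[i]),
                c(st$p2r[i], st$p2c[i]), c(st$p3r[i], st$p3c[i]))
    strand_spec(cp, thickness = st$thickness[i], arc_length = st$arc_length[i])
  })
  new_hair_mask(x, specs, working_size = m$working_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat numeric table of strand specs; (row, col) coordinates, 0-based
mask_metadata <- function(mask) {
  specs <- mask$strand_specs
  cp <- lapply(specs, `[[`, "control_points")
  strands <- list(
    p0r = vapply(cp, function(p) p[1, 1], 0), p0c = vapply(cp, function(p) p[1, 2], 0),
    p1r = vapply(cp, function(p) p[2, 1], 0), p1c = vapply(cp, function(p) p[2, 2], 0),
    p2r = vapply(cp, function(p) p[3, 1], 0), p2c = vapply(cp, function(p) p[3, 2], 0),
    p3r = vapply(cp, function(p) p[4, 1], 0), p3c = vapply(cp, function(p) p[4, 2], 0),
    thickness = vapply(specs, `[[`, 0, "thickness"),
    arc_length = vapply(specs, `[[`, 0, "arc_length"))
  list(strand_count = mask$strand_count, working_size = mask$working_size,
       strands = strands)
}
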