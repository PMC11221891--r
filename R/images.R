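#' Read an RGB image
#'
#' Reads a PNG or TIFF file into the package's internal image representation:
#' a numeric `H x W x 3` array with channel values on the 0--255 scale
#' (`H` rows = vertical/y axis, `W` columns = horizontal/x axis).
#' Grayscale images are expanded to three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array of dimension `H x W x 3`, values in `[0, 255]`.
#' @export
read_image <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "' (expected png/tif/tiff)")
  )
  if (length(dim(img)) == 2L) {
    img <- array(img, c(dim(img), 1L))
  }
  nc <- dim(img)[3L]
  if (nc == 1L) {
    img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  } else if (nc >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    stop("unsupported channel count: ", nc)
  }
  img * 255
}

#' Write an RGB image
#'
#' Writes an `H x W x 3` array (0--255 scale) as PNG or TIFF, chosen from the
#' file extension.
#'
#' @param image Numeric `H x W x 3` array, values in `[0, 255]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  scaled <- pmin(pmax(image / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(scaled, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(scaled, where = path),
    stop("unsupported image format: '", ext, "'")
  )
  invisible(path)
}

check_image <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3L] == 3L)) {
    stop("image must be an H x W x 3 array")
  }
  invisible(TRUE)
}

# Row/column interpolation weights for bilinear resampling with the
# half-pixel-center convention: output pixel i (0-based) samples input
# coordinate (i + 0.5) * n_in / n_out - 0.5, clamped to [0, n_in - 1].
# Returned as a dense n_out x n_in matrix so a channel resizes as R %*% X %*% t(C).
bilinear_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  hi <- pmin(lo + 1, n_in - 1)
  w <- src - lo
  idx <- seq_len(n_out)
  M[cbind(idx, lo + 1)] <- M[cbind(idx, lo + 1)] + (1 - w)
  M[cbind(idx, hi + 1)] <- M[cbind(idx, hi + 1)] + w
  M
}

#' Resize a square RGB patch
#'
#' Bilinear resampling (half-pixel-center convention, edge-clamped) of a
#' square patch to `target_side` pixels. The same routine serves both the
#' down-scaling of valid whole-slide tiles to the network input size and any
#' working-resolution reduction of spot patches.
#'
#' @param patch Square `s x s x 3` numeric array (0--255 scale).
#' @param target_side Positive integer, side length of the output.
#' @return `target_side x target_side x 3` numeric array.
#' @export
resize_patch <- function(patch, target_side) {
  check_image(patch)
  d <- dim(patch)
  if (d[1L] != d[2L]) {
    stop("resize_patch requires a square input, got ", d[1L], " x ", d[2L])
  }
  stopifnot(target_side >= 1)
  if (d[1L] == target_side) {
    return(patch)
  }
  R <- bilinear_matrix(d[1L], target_side)
  Ct <- t(bilinear_matrix(d[2L], target_side))
  out <- array(0, c(target_side, target_side, 3L))
  for (ch in 1:3) out[, , ch] <- R %*% patch[, , ch] %*% Ct
  out
}

# Resize every patch in a stack (n-array H x W x 3 x n) to `side`.
resize_stack <- function(patches, side) {
  d <- dim(patches)
  if (d[1L] == side && d[2L] == side) {
    return(patches)
  }
  out <- array(0, c(side, side, 3L, d[4L]))
  for (i in seq_len(d[4L])) {
    out[, , , i] <- resize_patch(patches[, , , i, drop = TRUE], side)
  }
  out
}
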