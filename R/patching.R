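#' Spot tables
#'
#' A spot table is the spatial skeleton of one sample: a `data.frame` with
#' columns `spot_id` (unique character ids), `x`, `y` (non-negative integer
#' pixel or tile coordinates; `x` is horizontal/column, `y` vertical/row,
#' 0-based) and optionally `label` (`"tumor"` / `"non_tumor"`, `NA` when
#' unknown). All rows of one table refer to one image.
#'
#' @param spots A candidate spot table.
#' @return The validated spot table (invisibly for `check_spot_table`).
#' @name spot_table
NULL

check_spot_table <- function(spots) {
  stopifnot(is.data.frame(spots))
  if (!all(c("spot_id", "x", "y") %in% names(spots))) {
    stop("spot table needs columns spot_id, x, y")
  }
  if (anyDuplicated(spots$spot_id)) {
    stop("spot_id values must be unique within a sample")
  }
  if (any(spots$x < 0) || any(spots$y < 0)) {
    stop("spot coordinates must be non-negative")
  }
  if ("label" %in% names(spots)) {
    bad <- !is.na(spots$label) & !spots$label %in% c("tumor", "non_tumor")
    if (any(bad)) stop("labels must be 'tumor' or 'non_tumor'")
  }
  invisible(spots)
}

#' @rdname spot_table
#' @param path TSV file with header `spot_id  x  y  [label]`.
#' @export
read_spot_table <- function(path) {
  spots <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c(spot_id = "character"))
  check_spot_table(spots)
  spots
}

#' @rdname spot_table
#' @export
write_spot_table <- function(spots, path) {
  check_spot_table(spots)
  utils::write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Crop coordinate-centered spot patches
#'
#' Extracts one square patch per spot from a spatial-transcriptomics image.
#' The crop window for a spot at `(x, y)` is the half-open pixel range
#' `[x - half_side, x + half_side) x [y - half_side, y + half_side)` in
#' 0-based coordinates, so the patch side is exactly `2 * half_side`
#' (224 pixels for the default `half_side = 112`). A window that leaves the
#' image is an error naming the offending spot; nothing is clamped silently.
#'
#' @param image `H x W x 3` numeric array (0--255 scale).
#' @param spots Spot table (see [read_spot_table()]).
#' @param half_side Half the patch side in pixels (default 112).
#' @return Patch stack: a `side x side x 3 x g` array whose fourth margin is
#'   named by `spot_id` and ordered like `spots`.
#' @export
crop_spot_patches <- function(image, spots, half_side = 112L) {
  check_image(image)
  check_spot_table(spots)
  stopifnot(half_side >= 1)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  side <- 2L * as.integer(half_side)
  g <- nrow(spots)
  out <- array(0, c(side, side, 3L, g),
               dimnames = list(NULL, NULL, NULL, spots$spot_id))
  for (i in seq_len(g)) {
    x <- spots$x[i]; y <- spots$y[i]
    r0 <- y - half_side; c0 <- x - half_side      # 0-based inclusive start
    r1 <- y + half_side; c1 <- x + half_side      # 0-based exclusive end
    if (r0 < 0 || c0 < 0 || r1 > H || c1 > W) {
      stop(sprintf(
        "spot '%s' at (%d, %d): crop window [%d,%d) x [%d,%d) exceeds %d x %d image",
        spots$spot_id[i], x, y, c0, c1, r0, r1, H, W))
    }
    out[, , , i] <- image[(r0 + 1):r1, (c0 + 1):c1, ]
  }
  out
}

#' Tile a whole-slide image into candidate spots
#'
#' Whole-slide images carry no spot coordinates, so the image is divided into
#' non-overlapping `tile_side x tile_side` tiles scanned row-major from the
#' top-left corner (trailing partial tiles are discarded). A pixel counts as
#' foreground when the arithmetic mean of its three channel values is below
#' `rgb_threshold`; a tile is a valid spot when at least
#' `min_fg_fraction * tile_side^2` of its pixels are foreground, otherwise it
#' is background and dropped. Valid tiles are resized (bilinear) to
#' `out_side` pixels, and their integer tile indices are recorded as the spot
#' coordinates (`x` = row index, `y` = column index, 0-based), so adjacent
#' tiles are at distance 1 in the spot graph.
#'
#' @param image `H x W x 3` numeric array (0--255 scale).
#' @param tile_side Tile side in pixels (default 512).
#' @param rgb_threshold Foreground threshold on per-pixel channel means
#'   (default 220).
#' @param min_fg_fraction Minimum foreground fraction for a valid tile
#'   (default 0.5; a tile with exactly half foreground pixels is valid).
#' @param out_side Side of the resized output patches (default 224).
#' @return List with `spots` (spot table of valid tiles) and `patches`
#'   (`out_side x out_side x 3 x n` stack). An image smaller than one tile
#'   yields an empty result with a warning.
#' @export
tile_wsi <- function(image, tile_side = 512L, rgb_threshold = 220,
                     min_fg_fraction = 0.5, out_side = 224L) {
  check_image(image)
  stopifnot(tile_side >= 2, min_fg_fraction >= 0, min_fg_fraction <= 1)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  nr <- H %/% tile_side; nc <- W %/% tile_side
  empty <- list(
    spots = data.frame(spot_id = character(0), x = integer(0), y = integer(0),
                       stringsAsFactors = FALSE),
    patches = array(0, c(out_side, out_side, 3L, 0L)))
  if (nr < 1L || nc < 1L) {
    warning("image (", H, " x ", W, ") smaller than one ", tile_side,
            "-pixel tile; returning empty result")
    return(empty)
  }
  min_count <- min_fg_fraction * tile_side^2
  pixel_mean <- (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
  ids <- character(0); xs <- integer(0); ys <- integer(0)
  keep <- list()
  for (r in 0:(nr - 1L)) {
    for (cc in 0:(nc - 1L)) {
      rows <- (r * tile_side + 1L):((r + 1L) * tile_side)
      cols <- (cc * tile_side + 1L):((cc + 1L) * tile_side)
      fg <- sum(pixel_mean[rows, cols] < rgb_threshold)
      if (fg >= min_count) {
        ids <- c(ids, sprintf("tile_r%d_c%d", r, cc))
        xs <- c(xs, r); ys <- c(ys, cc)
        keep[[length(keep) + 1L]] <-
          resize_patch(image[rows, cols, , drop = FALSE], out_side)
      }
    }
  }
  if (length(keep) == 0L) {
    return(empty)
  }
  patches <- array(0, c(out_side, out_side, 3L, length(keep)),
                   dimnames = list(NULL, NULL, NULL, ids))
  for (i in seq_along(keep)) patches[, , , i] <- keep[[i]]
  list(spots = data.frame(spot_id = ids, x = xs, y = ys,
                          stringsAsFactors = FALSE),
       patches = patches)
}

#' Persist or load a patch stack
#'
#' A patch stack is stored as a directory of PNG files named
#' `{spot_id}.png` plus the spot-table TSV manifest, so extracted patches can
#' be inspected with any image viewer and reloaded in the manifest order.
#'
#' @param patches `side x side x 3 x g` array (fourth margin named by spot id).
#' @param spots Matching spot table.
#' @param dir Output/input directory.
#' @return `dir` (write) or a list `spots`/`patches` (read).
#' @export
write_patch_stack <- function(patches, spots, dir) {
  check_spot_table(spots)
  stopifnot(dim(patches)[4L] == nrow(spots))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spot_table(spots, file.path(dir, "spots.tsv"))
  for (i in seq_len(nrow(spots))) {
    write_image(patches[, , , i, drop = TRUE],
                file.path(dir, paste0(spots$spot_id[i], ".png")))
  }
  invisible(dir)
}

#' @rdname write_patch_stack
#' @export
read_patch_stack <- function(dir) {
  spots <- read_spot_table(file.path(dir, "spots.tsv"))
  first <- read_image(file.path(dir, paste0(spots$spot_id[1L], ".png")))
  side <- dim(first)[1L]
  patches <- array(0, c(side, side, 3L, nrow(spots)),
                   dimnames = list(NULL, NULL, NULL, spots$spot_id))
  patches[, , , 1L] <- first
  for (i in seq_len(nrow(spots))[-1L]) {
    patches[, , , i] <- read_image(file.path(dir, paste0(spots$spot_id[i], ".png")))
  }
  list(spots = spots, patches = patches)
}
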