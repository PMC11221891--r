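#' Pairwise Euclidean distances between spots
#'
#' @param spots Spot table with `x`, `y` coordinates.
#' @return Symmetric `g x g` matrix of Euclidean distances, zero diagonal,
#'   rows/columns named by `spot_id`. Duplicate coordinates are allowed
#'   (distance 0) but reported with a message.
#' @export
pairwise_distances <- function(spots) {
  check_spot_table(spots)
  xy <- cbind(spots$x, spots$y)
  d <- as.matrix(stats::dist(xy, method = "euclidean"))
  dimnames(d) <- list(spots$spot_id, spots$spot_id)
  if (nrow(spots) > 1L && any(d[upper.tri(d)] == 0)) {
    message("duplicate spot coordinates present (zero off-diagonal distance)")
  }
  d
}

#' Build the binary spot adjacency matrix
#'
#' For each spot, its distances to all other spots are normalized by the
#' maximum of that row; spot `j` is a neighbor of spot `i` when the
#' normalized distance is strictly below `threshold`. The diagonal is forced
#' to zero (no self-connections). Because the normalization is per-row, the
#' resulting graph may be asymmetric; `symmetrize = TRUE` takes the logical
#' OR with the transpose. A single-spot sample yields a 1x1 zero matrix with
#' a warning. Isolated spots (no neighbors) are permitted: the attention
#' layer's self-coefficient handles them.
#'
#' @param spots Spot table.
#' @param threshold Fraction in `(0, 1]` applied to row-normalized distances
#'   (default 0.1).
#' @param symmetrize Logical; default `FALSE` (the attention layer consumes
#'   row-wise neighbor sets).
#' @return Binary `g x g` matrix with zero diagonal; `entries[i, j] = 1`
#'   means `j` is a neighbor of `i`.
#' @export
build_adjacency <- function(spots, threshold = 0.1, symmetrize = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  d <- pairwise_distances(spots)
  g <- nrow(d)
  if (g == 1L) {
    warning("single spot: adjacency has no neighbors")
    return(matrix(0, 1, 1, dimnames = dimnames(d)))
  }
  rmax <- apply(d, 1L, max)
  rmax[rmax == 0] <- 1          # all-coincident row: keep zeros, no division by 0
  dn <- d / rmax                # row-wise normalization
  adj <- (dn < threshold) * 1
  diag(adj) <- 0
  if (symmetrize) adj <- pmax(adj, t(adj))
  adj
}

check_adjacency <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero")
  if (!all(adj %in% c(0, 1))) stop("adjacency entries must be binary")
  invisible(adj)
}

#' Read/write an adjacency matrix as a TSV edge list
#'
#' Edges are stored one per line as `src  dst` spot ids (directed: `dst` is
#' a neighbor of `src`).
#'
#' @param adj Binary adjacency matrix with spot-id dimnames.
#' @param path TSV path.
#' @param spot_ids Character vector fixing node order on read.
#' @export
write_adjacency <- function(adj, path) {
  check_adjacency(adj)
  idx <- which(adj == 1, arr.ind = TRUE)
  edges <- data.frame(src = rownames(adj)[idx[, 1L]],
                      dst = colnames(adj)[idx[, 2L]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$src, edges$dst), , drop = FALSE]
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path, spot_ids) {
  edges <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character")
  adj <- matrix(0, length(spot_ids), length(spot_ids),
                dimnames = list(spot_ids, spot_ids))
  if (nrow(edges) > 0L) {
    if (!all(edges$src %in% spot_ids) || !all(edges$dst %in% spot_ids)) {
      stop("edge list references unknown spot ids")
    }
    adj[cbind(edges$src, edges$dst)] <- 1
  }
  adj
}
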