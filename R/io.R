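#' Expression and bulk TSV input/output
#'
#' Spot expression matrices are stored as TSV with a `spot_id` first column
#' and one column per gene; bulk vectors as two-column TSV
#' `gene_id  value`.
#'
#' @param expr `g x p` matrix (rows named by spot id, columns by gene).
#' @param bulk Named numeric vector.
#' @param path TSV path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(spot_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' @rdname write_expression
#' @export
write_bulk <- function(bulk, path) {
  df <- data.frame(gene_id = names(bulk), value = unname(bulk),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_bulk <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(df$value, df$gene_id)
}

#' Save or load a model checkpoint
#'
#' Model states (SEG / GEP / SLP) are serialized with their configuration
#' and restored bit-exactly.
#'
#' @param state A `seg_state`, `gep_state` or `slp_state`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, c("seg_state", "gep_state", "slp_state")))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, c("seg_state", "gep_state", "slp_state")))
  state
}

#' Intersect the gene sets of two expression sources
#'
#' Exact-name intersection utility used when pairing spatial and bulk
#' cohorts profiled over different gene universes.
#'
#' @param genes_a,genes_b Character vectors of gene ids.
#' @return Character vector of shared ids, in the order of `genes_a`.
#' @export
intersect_genes <- function(genes_a, genes_b) {
  genes_a[genes_a %in% genes_b]
}
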