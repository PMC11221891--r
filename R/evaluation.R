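#' Per-sample correlation between predicted and true expression
#'
#' Pearson correlation over all `g * p` paired entries of one sample's
#' predicted and true spot-by-gene matrices (one value per sample; set
#' `per_spot = TRUE` for a per-spot breakdown instead).
#'
#' @param pred,truth `g x p` matrices of identical dimension.
#' @param per_spot If `TRUE`, return one correlation per spot (across its
#'   `p` genes) instead of the flattened per-sample value.
#' @return Scalar in `[-1, 1]`, or a length-`g` vector when `per_spot`.
#' @export
sample_correlation <- function(pred, truth, per_spot = FALSE) {
  stopifnot(all(dim(pred) == dim(truth)))
  if (per_spot) {
    return(vapply(seq_len(nrow(pred)),
                  function(i) stats::cor(pred[i, ], truth[i, ]), numeric(1)))
  }
  stats::cor(as.vector(pred), as.vector(truth))
}

#' Per-sample mean squared error
#'
#' @param pred,truth `g x p` matrices of identical dimension.
#' @return Mean squared entrywise difference.
#' @export
sample_mse <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  mean((pred - truth)^2)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, with ties counted 1/2
#' (computed from midranks).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary 0/1 vector; both classes must be present.
#' @return Fraction in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) stop("auroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Rank candidate marker genes between tumor and non-tumor spots
#'
#' Selects the `top_var` genes with the largest variance across spots, then
#' orders them by the two-sided Welch t-test p-value comparing tumor versus
#' non-tumor spots (ascending). A gene with zero variance inside both
#' groups gets p-value 1. Raw p-values are reported; a Benjamini-Hochberg
#' adjusted column is included for convenience.
#'
#' @param expr `g x p` expression matrix with gene column names.
#' @param labels Binary 0/1 (or `"tumor"`/`"non_tumor"`) vector of length
#'   `g`; both classes must be present.
#' @param top_var Number of top-variance genes to test (default
#'   `min(100, ncol(expr))`).
#' @return `data.frame` with columns `gene`, `t`, `p_value`, `p_adj`,
#'   ordered by ascending p-value.
#' @export
rank_marker_genes <- function(expr, labels, top_var = min(100L, ncol(expr))) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == "tumor")
  }
  labels <- as.integer(labels)
  stopifnot(nrow(expr) == length(labels), top_var <= ncol(expr), top_var >= 1)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("gene_", seq_len(ncol(expr)))
  }
  vars <- apply(expr, 2L, stats::var)
  sel <- order(vars, decreasing = TRUE)[seq_len(top_var)]
  res <- lapply(sel, function(j) {
    x <- expr[labels == 1L, j]
    y <- expr[labels == 0L, j]
    tt <- tryCatch(stats::t.test(x, y),
                   error = function(e) NULL)     # constant data -> no evidence
    if (is.null(tt)) data.frame(gene = colnames(expr)[j], t = 0, p_value = 1)
    else data.frame(gene = colnames(expr)[j], t = unname(tt$statistic),
                    p_value = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
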