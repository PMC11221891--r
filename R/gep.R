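#' Configuration for the gene expression predictor (GEP)
#'
#' The GEP fuses frozen spot embeddings from a pretrained SEG with a learned
#' embedding of the sample's bulk RNA-seq profile. The bulk vector passes
#' through two fully connected layers; the spot-embedding matrix and the
#' bulk embedding are multiplied by the learnable alignment matrices
#' `W_spots` and `W_bulk`, z-score normalized, and summed (the normalized
#' bulk embedding is broadcast to every spot); three decoder layers then
#' emit per-spot expression. Training matches the spot-average prediction to
#' the true bulk profile.
#'
#' @param embed_dim Embedding length `e` (must equal the SEG checkpoint's
#'   `n_heads * embed_attn`).
#' @param n_genes Number of genes `p`.
#' @param bulk_hidden Hidden width of the two-layer bulk encoder
#'   (default 256).
#' @param decoder_hidden Hidden width of the first two decoder layers
#'   (default 256).
#' @param learning_rate,epochs,seed Optimization settings (Adam).
#' @return A `gep_config` list.
#' @export
gep_config <- function(embed_dim, n_genes, bulk_hidden = 256L,
                       decoder_hidden = 256L, learning_rate = 1e-3,
                       epochs = 1600L, seed = 1L) {
  structure(list(embed_dim = as.integer(embed_dim),
                 n_genes = as.integer(n_genes),
                 bulk_hidden = as.integer(bulk_hidden),
                 decoder_hidden = as.integer(decoder_hidden),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "gep_config")
}

gep_init <- function(cfg) {
  stopifnot(inherits(cfg, "gep_config"))
  e <- cfg$embed_dim
  params <- list(
    enc1 = linear_init(cfg$n_genes, cfg$bulk_hidden),
    enc2 = linear_init(cfg$bulk_hidden, e),
    W_spots = matrix(stats::rnorm(e * e, sd = sqrt(1 / e)), e, e),
    W_bulk = matrix(stats::rnorm(e * e, sd = sqrt(1 / e)), e, e),
    dec1 = linear_init(e, cfg$decoder_hidden),
    dec2 = linear_init(cfg$decoder_hidden, cfg$decoder_hidden),
    dec3 = linear_init(cfg$decoder_hidden, cfg$n_genes,
                       sd = sqrt(1 / cfg$decoder_hidden))
  )
  structure(list(cfg = cfg, params = params, gene_ids = NULL),
            class = "gep_state")
}

# population z-score along a vector, with a small guard against zero spread
zscore_eps <- 1e-8
zscore_vec <- function(x) {
  mu <- mean(x)
  sd_ <- sqrt(mean((x - mu)^2) + zscore_eps)   # eps inside the root keeps the
  list(xhat = (x - mu) / sd_, sd = sd_)        # gradient formula exact
}

#' GEP forward pieces
#'
#' `encode_bulk` maps a bulk expression vector to a length-`e` embedding
#' `Z1` through the two-layer bulk encoder. `align_and_fuse` computes
#' `E4 = W_spots %*% t(E3)` and `Z2 = W_bulk %*% Z1`, z-score normalizes
#' `E4` per feature across spots and `Z2` across its `e` entries, and adds
#' the normalized bulk embedding to every spot column, giving the fused
#' `e x m` representation `Z3`. `decode_spots` runs the three decoder
#' layers on the spot columns of `Z3`, producing the `m x p` expression
#' prediction.
#'
#' @param bulk Length-`p` numeric bulk expression vector.
#' @param E3 `m x e` frozen spot-embedding matrix from [seg_embed()].
#' @param Z1 Length-`e` bulk embedding.
#' @param Z3 `e x m` fused representation.
#' @param state A `gep_state`.
#' @return See each piece above.
#' @export
encode_bulk <- function(bulk, state) {
  stopifnot(length(bulk) == state$cfg$n_genes)
  h <- relu(linear_forward(matrix(bulk, 1L), state$params$enc1))
  drop(linear_forward(h, state$params$enc2))
}

#' @rdname encode_bulk
#' @export
align_and_fuse <- function(E3, Z1, state) {
  m <- nrow(E3)
  if (m < 2L) {
    stop("align_and_fuse needs at least 2 spots: per-feature z-score ",
         "normalization across spots is degenerate for m = 1")
  }
  E4 <- state$params$W_spots %*% t(E3)            # e x m
  Z2 <- drop(state$params$W_bulk %*% Z1)          # e
  mu <- rowMeans(E4)
  sd_ <- sqrt(rowMeans((E4 - mu)^2) + zscore_eps)
  E5 <- (E4 - mu) / sd_
  Z2n <- zscore_vec(Z2)$xhat
  E5 + Z2n                                        # broadcast add per column
}

#' @rdname encode_bulk
#' @export
decode_spots <- function(Z3, state) {
  X <- t(Z3)                                      # m x e
  h1 <- relu(linear_forward(X, state$params$dec1))
  h2 <- relu(linear_forward(h1, state$params$dec2))
  Y <- linear_forward(h2, state$params$dec3)
  if (!is.null(state$gene_ids)) colnames(Y) <- state$gene_ids
  Y
}

#' Bulk-reconstruction loss of the GEP
#'
#' The spot-average of the predicted expression (column mean over spots) is
#' taken as the sample's predicted bulk profile and compared to the true
#' bulk vector by mean squared error.
#'
#' @param pred `m x p` predicted spot expression.
#' @param bulk Length-`p` true bulk vector.
#' @return Scalar loss.
#' @export
gep_loss <- function(pred, bulk) {
  stopifnot(ncol(pred) == length(bulk))
  U <- colMeans(pred)
  mean((U - bulk)^2)
}

gep_forward_train <- function(E3, bulk, state) {
  p <- state$params
  m <- nrow(E3)
  X1 <- matrix(bulk, 1L)
  h1pre <- linear_forward(X1, p$enc1)
  h1 <- relu(h1pre)
  Z1 <- drop(linear_forward(h1, p$enc2))
  E4 <- p$W_spots %*% t(E3)
  Z2 <- drop(p$W_bulk %*% Z1)
  mu <- rowMeans(E4)
  sdE <- sqrt(rowMeans((E4 - mu)^2) + zscore_eps)
  E5 <- (E4 - mu) / sdE
  zs <- zscore_vec(Z2)
  Z3 <- E5 + zs$xhat
  Xd <- t(Z3)
  d1pre <- linear_forward(Xd, p$dec1)
  d1 <- relu(d1pre)
  d2pre <- linear_forward(d1, p$dec2)
  d2 <- relu(d2pre)
  Y <- linear_forward(d2, p$dec3)
  U <- colMeans(Y)
  loss <- mean((U - bulk)^2)
  list(loss = loss, Y = Y,
       cache = list(X1 = X1, h1pre = h1pre, h1 = h1, Z1 = Z1, E4 = E4,
                    Z2 = Z2, sdE = sdE, E5 = E5, zs = zs, Xd = Xd,
                    d1pre = d1pre, d1 = d1, d2pre = d2pre, d2 = d2,
                    U = U, m = m))
}

# backward through the z-score: dx = (dy - mean(dy) - xhat * mean(dy*xhat)) / sd
zscore_backward_rows <- function(dY, xhat, sd_) {
  (dY - rowMeans(dY) - xhat * rowMeans(dY * xhat)) / sd_
}

gep_backward <- function(fw, bulk, E3, state) {
  p <- state$params
  ch <- fw$cache
  m <- ch$m
  grads <- tree_map(function(x) x * 0, p)

  dU <- 2 * (ch$U - bulk) / length(bulk)
  dY <- matrix(dU, m, length(bulk), byrow = TRUE) / m
  lb <- linear_backward(dY, ch$d2, p$dec3)
  grads$dec3$W <- lb$dW; grads$dec3$b <- lb$db
  dd2 <- relu_grad(lb$dX, ch$d2pre)
  lb <- linear_backward(dd2, ch$d1, p$dec2)
  grads$dec2$W <- lb$dW; grads$dec2$b <- lb$db
  dd1 <- relu_grad(lb$dX, ch$d1pre)
  lb <- linear_backward(dd1, ch$Xd, p$dec1)
  grads$dec1$W <- lb$dW; grads$dec1$b <- lb$db
  dZ3 <- t(lb$dX)                                 # e x m

  dE5 <- dZ3
  dZ2n <- rowSums(dZ3)
  dE4 <- zscore_backward_rows(dE5, ch$E5, ch$sdE)
  dZ2 <- drop(zscore_backward_rows(matrix(dZ2n, 1L), matrix(ch$zs$xhat, 1L),
                                   ch$zs$sd))
  grads$W_spots <- dE4 %*% E3
  grads$W_bulk <- outer(dZ2, ch$Z1)
  dZ1 <- drop(t(p$W_bulk) %*% dZ2)
  lb <- linear_backward(matrix(dZ1, 1L), ch$h1, p$enc2)
  grads$enc2$W <- lb$dW; grads$enc2$b <- lb$db
  dh1 <- relu_grad(lb$dX, ch$h1pre)
  lb <- linear_backward(dh1, ch$X1, p$enc1)
  grads$enc1$W <- lb$dW; grads$enc1$b <- lb$db
  grads
}

#' Train the gene expression predictor
#'
#' Spot embeddings are computed once through the frozen pretrained SEG (its
#' parameters are not touched), then the GEP parameters are optimized with
#' Adam so that each sample's predicted spot-average reconstructs its bulk
#' profile. Seeded and reproducible. The bulk objective is matched within a
#' few hundred epochs, but the decoder's use of the spot embeddings (what
#' resolves expression *within* a sample) keeps improving well beyond that,
#' hence the long default training schedule.
#'
#' @param samples List of samples, each a list with `patches`, `adj` and
#'   `bulk` (named length-`p` vector; names must match the SEG gene ids).
#' @param seg Trained `seg_state` (frozen).
#' @param cfg A [gep_config()]; `embed_dim` must match the SEG embedding.
#' @param verbose Print the mean loss every 50 epochs.
#' @return Trained `gep_state`.
#' @export
train_gep <- function(samples, seg, cfg, verbose = FALSE) {
  stopifnot(inherits(seg, "seg_state"), length(samples) >= 1L)
  e <- seg$cfg$n_heads * seg$cfg$embed_attn
  if (cfg$embed_dim != e) {
    stop("cfg$embed_dim (", cfg$embed_dim, ") does not match the SEG ",
         "embedding length (", e, ")")
  }
  for (s in samples) {
    if (!is.null(names(s$bulk)) && !is.null(seg$gene_ids) &&
        !identical(names(s$bulk), seg$gene_ids)) {
      stop("bulk gene set does not match the SEG gene set")
    }
    stopifnot(length(s$bulk) == cfg$n_genes)
  }
  emb <- lapply(samples, function(s) seg_embed(s$patches, s$adj, seg))
  set.seed(cfg$seed)
  state <- gep_init(cfg)
  state$gene_ids <- seg$gene_ids
  opt <- adam_init(state$params)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    losses <- numeric(length(samples))
    for (i in seq_along(samples)) {
      fw <- gep_forward_train(emb[[i]], samples[[i]]$bulk, state)
      grads <- gep_backward(fw, samples[[i]]$bulk, emb[[i]], state)
      upd <- adam_step(state$params, grads, opt, lr = cfg$learning_rate)
      state$params <- upd$params
      opt <- upd$opt
      losses[i] <- fw$loss
    }
    history[epoch] <- mean(losses)
    if (verbose && (epoch %% 50L == 0L || epoch == 1L)) {
      message(sprintf("epoch %d: bulk loss %.5f", epoch, history[epoch]))
    }
  }
  state$loss_history <- history
  state
}

#' Predict spot-level expression for a bulk-profiled sample
#'
#' Runs the full transfer path: frozen SEG embeddings of the sample's spot
#' patches, fusion with the encoded bulk profile, and decoding to per-spot
#' expression.
#'
#' @param patches Spot patch stack (`side x side x 3 x m`, 0--255).
#' @param adj Binary spot adjacency.
#' @param bulk Named length-`p` bulk expression vector.
#' @param seg Trained `seg_state`.
#' @param gep Trained `gep_state`.
#' @return `m x p` matrix of predicted spot expression (rows named by spot
#'   id when the patch stack carries them).
#' @export
predict_spot_expression <- function(patches, adj, bulk, seg, gep) {
  E3 <- seg_embed(patches, adj, seg)
  Z1 <- encode_bulk(bulk, gep)
  Z3 <- align_and_fuse(E3, Z1, gep)
  Y <- decode_spots(Z3, gep)
  ids <- dimnames(patches)[[4L]]
  if (!is.null(ids)) rownames(Y) <- ids
  Y
}
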