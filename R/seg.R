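#' Configuration for the spot embedding generator (SEG)
#'
#' The SEG maps spot images plus the spatial adjacency to per-spot gene
#' expression. It stacks convolutional blocks (conv 3x3 + ReLU, each block
#' except the first followed by a 2x2 max-pool), a flatten-to-`embed_cnn`
#' linear projection, an intermediate fully connected layer, a
#' dual-coefficient multi-head graph-attention layer, and a two-layer
#' expression head.
#'
#' @param n_genes Number of genes `p` predicted per spot.
#' @param patch_side Input patch side in pixels (default 224). Spot patches
#'   are bilinearly resized to this side before entering the network.
#' @param conv_channels Integer vector of output channels per block
#'   (default `c(32, 64, 64, 128, 128, 256)`, six blocks).
#' @param pool Logical vector, whether each block ends in a 2x2 max-pool.
#'   Default: every block but the first.
#' @param embed_cnn CNN embedding length `e_c` (default 512).
#' @param embed_attn Per-head attention embedding length `e_a` (default 256);
#'   the concatenated embedding has length `e = n_heads * embed_attn`.
#' @param n_heads Number of attention heads `h` (default 2).
#' @param head_hidden Hidden width of the two-layer expression head
#'   (default `embed_cnn`).
#' @param head_nonlinearity Nonlinearity `f` applied to each head's output:
#'   `"relu"` (default) or `"elu"`.
#' @param tie_value_weights If `TRUE`, the per-head value matrices are tied
#'   to the attention-score matrices `W_s`, `W_n`; default `FALSE` (separate
#'   value matrices `W'_s`, `W'_n`).
#' @param alpha_mode `"post_softmax"` (default): the self-coefficient is
#'   computed from the softmax-normalized neighbor coefficients, giving
#'   exactly 1/2 for any spot with neighbors and 1 for an isolated spot.
#'   `"pre_softmax"`: computed from the raw (pre-softmax) neighbor scores.
#' @param learning_rate,epochs,seed Optimization settings (Adam).
#' @return A `seg_config` list.
#' @export
seg_config <- function(n_genes,
                       patch_side = 224L,
                       conv_channels = c(32L, 64L, 64L, 128L, 128L, 256L),
                       pool = NULL,
                       embed_cnn = 512L,
                       embed_attn = 256L,
                       n_heads = 2L,
                       head_hidden = embed_cnn,
                       head_nonlinearity = c("relu", "elu"),
                       tie_value_weights = FALSE,
                       alpha_mode = c("post_softmax", "pre_softmax"),
                       learning_rate = 1e-3,
                       epochs = 200L,
                       seed = 1L) {
  head_nonlinearity <- match.arg(head_nonlinearity)
  alpha_mode <- match.arg(alpha_mode)
  nb <- length(conv_channels)
  if (is.null(pool)) pool <- c(FALSE, rep(TRUE, nb - 1L))
  stopifnot(length(pool) == nb, n_genes >= 1, embed_cnn >= 1,
            embed_attn >= 1, n_heads >= 1)
  side <- patch_side
  for (b in seq_len(nb)) {
    if (pool[b]) {
      if (side %% 2L != 0L) {
        stop("patch_side ", patch_side, " incompatible with pooling schedule ",
             "(odd spatial size ", side, " at block ", b, ")")
      }
      side <- side %/% 2L
    }
  }
  structure(list(
    n_genes = as.integer(n_genes), patch_side = as.integer(patch_side),
    conv_channels = as.integer(conv_channels), pool = pool,
    embed_cnn = as.integer(embed_cnn), embed_attn = as.integer(embed_attn),
    n_heads = as.integer(n_heads), head_hidden = as.integer(head_hidden),
    head_nonlinearity = head_nonlinearity,
    tie_value_weights = tie_value_weights, alpha_mode = alpha_mode,
    learning_rate = learning_rate, epochs = as.integer(epochs),
    seed = as.integer(seed),
    final_side = side, flat_dim = side * side * conv_channels[nb]
  ), class = "seg_config")
}

#' Initialize SEG parameters
#'
#' Draws fresh parameters for the configuration using the current RNG state
#' (seed it for reproducibility). Parameters: one conv layer per block, the
#' flatten projection, the intermediate FC (`W`, `B`), per-head attention
#' vectors `a_s`, `a_n` and score matrices `W_s`, `W_n` plus value matrices
#' `W'_s`, `W'_n`, and the two expression-head layers.
#'
#' @param cfg A [seg_config()].
#' @return A `seg_state` list (parameters in `$params`, config in `$cfg`).
#' @export
seg_init <- function(cfg) {
  stopifnot(inherits(cfg, "seg_config"))
  e_c <- cfg$embed_cnn; e_a <- cfg$embed_attn
  c_in <- 3L
  conv <- list()
  for (b in seq_along(cfg$conv_channels)) {
    conv[[b]] <- conv_init(3L, c_in, cfg$conv_channels[b])
    c_in <- cfg$conv_channels[b]
  }
  heads <- lapply(seq_len(cfg$n_heads), function(l) {
    hd <- list(a_s = stats::rnorm(e_a, sd = sqrt(1 / e_a)),
               a_n = stats::rnorm(e_a, sd = sqrt(1 / e_a)),
               W_s = matrix(stats::rnorm(e_a * e_c, sd = sqrt(2 / e_c)), e_a, e_c),
               W_n = matrix(stats::rnorm(e_a * e_c, sd = sqrt(2 / e_c)), e_a, e_c))
    if (!cfg$tie_value_weights) {
      hd$Wv_s <- matrix(stats::rnorm(e_a * e_c, sd = sqrt(2 / e_c)), e_a, e_c)
      hd$Wv_n <- matrix(stats::rnorm(e_a * e_c, sd = sqrt(2 / e_c)), e_a, e_c)
    }
    hd
  })
  params <- list(
    conv = conv,
    proj = linear_init(cfg$flat_dim, e_c),
    fc1 = linear_init(e_c, e_c),
    heads = heads,
    head1 = linear_init(cfg$n_heads * e_a, cfg$head_hidden),
    head2 = linear_init(cfg$head_hidden, cfg$n_genes,
                        sd = sqrt(1 / cfg$head_hidden))
  )
  structure(list(cfg = cfg, params = params, gene_ids = NULL),
            class = "seg_state")
}

head_value_mats <- function(hd, cfg) {
  if (cfg$tie_value_weights) list(Wv_s = hd$W_s, Wv_n = hd$W_n)
  else list(Wv_s = hd$Wv_s, Wv_n = hd$Wv_n)
}

head_f <- function(x, kind) {
  if (kind == "relu") pmax(x, 0) else ifelse(x > 0, x, exp(x) - 1)
}
head_f_grad <- function(dOut, pre, kind) {
  if (kind == "relu") dOut * (pre > 0) else dOut * ifelse(pre > 0, 1, exp(pre))
}

# --- forward pieces --------------------------------------------------------

seg_cnn_forward <- function(patches, state, keep_cache = FALSE) {
  cfg <- state$cfg
  d <- dim(patches)
  if (d[1L] != cfg$patch_side || d[2L] != cfg$patch_side || d[3L] != 3L) {
    stop("patches must be ", cfg$patch_side, " x ", cfg$patch_side,
         " x 3, got ", paste(d[1:3], collapse = " x "))
  }
  X <- patches / 255                              # fixed [0, 1] pixel scaling
  caches <- list()
  for (b in seq_along(state$params$conv)) {
    cv <- conv_forward(X, state$params$conv[[b]])
    A <- relu(cv$out)
    blk <- list(conv = cv$cache, pre = cv$out)
    if (cfg$pool[b]) {
      mp <- maxpool_forward(A)
      X <- mp$out
      blk$pool <- mp$cache
    } else {
      X <- A
    }
    caches[[b]] <- blk
  }
  g <- d[4L]
  flat <- t(matrix(X, cfg$flat_dim, g))           # g x flat_dim
  E1pre <- linear_forward(flat, state$params$proj)
  E1 <- relu(E1pre)
  res <- list(E1 = E1)
  if (keep_cache) res$cache <- list(blocks = caches, flat = flat, E1pre = E1pre)
  res
}

#' SEG forward pieces
#'
#' `cnn_encode` runs the convolutional blocks plus the flatten projection,
#' producing the `g x e_c` embedding `E1` (pixel values are scaled to
#' `[0, 1]` internally). `intermediate_fc` applies the square intermediate
#' fully connected layer with ReLU, giving `E2`. `attention_coefficients`
#' computes one head's neighbor coefficients (masked softmax over each
#' spot's neighbor set) and self-coefficients. `gat_forward` runs all heads
#' and concatenates them into the `g x e` embedding `E3`; `expression_head`
#' maps `E3` to the `g x p` expression prediction.
#'
#' @param patches `side x side x 3 x g` patch stack (0--255 scale).
#' @param E1,E2,E3 Intermediate embeddings as returned by the previous stage.
#' @param adj Binary adjacency matrix from [build_adjacency()].
#' @param state A `seg_state`.
#' @param head Head index (1-based).
#' @return `cnn_encode`/`intermediate_fc`: a numeric matrix.
#'   `attention_coefficients`: list with `alpha_n` (`g x g`, rows summing to
#'   1 over each non-empty neighbor set) and `alpha_s` (length `g`; exactly
#'   0.5 for spots with neighbors and 1 for isolated spots in the default
#'   mode). `gat_forward`: `g x (n_heads * e_a)` matrix. `expression_head`:
#'   `g x p` matrix.
#' @export
cnn_encode <- function(patches, state) {
  seg_cnn_forward(patches, state)$E1
}

#' @rdname cnn_encode
#' @export
intermediate_fc <- function(E1, state) {
  relu(linear_forward(E1, state$params$fc1))
}

attention_scores <- function(E2, hd) {
  S_s <- E2 %*% t(hd$W_s)                         # g x e_a
  S_n <- E2 %*% t(hd$W_n)
  u <- drop(S_s %*% hd$a_s)                       # self part, per target spot
  w <- drop(S_n %*% hd$a_n)                       # neighbor part, per source
  z <- outer(u, rep(1, length(w))) + outer(rep(1, length(u)), w)
  list(S_s = S_s, S_n = S_n, u = u, w = w, z = z)
}

#' @rdname cnn_encode
#' @export
attention_coefficients <- function(E2, adj, state, head = 1L) {
  check_adjacency(adj)
  stopifnot(nrow(E2) == nrow(adj))
  cfg <- state$cfg
  hd <- state$params$heads[[head]]
  sc <- attention_scores(E2, hd)
  r <- relu(sc$z)
  support <- adj == 1
  alpha_n <- masked_softmax(r, support)
  has_nb <- rowSums(adj) > 0
  if (cfg$alpha_mode == "post_softmax") {
    alpha_s <- ifelse(has_nb, 1 / (1 + rowSums(alpha_n)), 1)
  } else {
    raw <- r
    raw[!support] <- 0
    alpha_s <- 1 / (1 + rowSums(raw))
  }
  list(alpha_n = alpha_n, alpha_s = alpha_s)
}

#' @rdname cnn_encode
#' @export
gat_forward <- function(E2, adj, state) {
  seg_gat_forward(E2, adj, state)$E3
}

seg_gat_forward <- function(E2, adj, state, keep_cache = FALSE) {
  check_adjacency(adj)
  cfg <- state$cfg
  g <- nrow(E2)
  support <- adj == 1
  has_nb <- rowSums(adj) > 0
  heads_out <- vector("list", cfg$n_heads)
  caches <- vector("list", cfg$n_heads)
  for (l in seq_len(cfg$n_heads)) {
    hd <- state$params$heads[[l]]
    vm <- head_value_mats(hd, cfg)
    sc <- attention_scores(E2, hd)
    r <- relu(sc$z)
    An <- masked_softmax(r, support)
    if (cfg$alpha_mode == "post_softmax") {
      alpha_s <- ifelse(has_nb, 1 / (1 + rowSums(An)), 1)
    } else {
      raw <- r; raw[!support] <- 0
      alpha_s <- 1 / (1 + rowSums(raw))
    }
    P <- E2 %*% t(vm$Wv_s)
    Q <- E2 %*% t(vm$Wv_n)
    pre <- alpha_s * P + An %*% Q
    heads_out[[l]] <- head_f(pre, cfg$head_nonlinearity)
    if (keep_cache) {
      caches[[l]] <- list(sc = sc, r = r, An = An, alpha_s = alpha_s,
                          P = P, Q = Q, pre = pre)
    }
  }
  E3 <- do.call(cbind, heads_out)
  res <- list(E3 = E3)
  if (keep_cache) res$cache <- list(heads = caches, support = support,
                                    has_nb = has_nb)
  res
}

#' @rdname cnn_encode
#' @export
expression_head <- function(E3, state) {
  A1 <- relu(linear_forward(E3, state$params$head1))
  Y <- linear_forward(A1, state$params$head2)
  if (!is.null(state$gene_ids)) colnames(Y) <- state$gene_ids
  Y
}

#' Full SEG forward pass
#'
#' @inheritParams cnn_encode
#' @param detach_head If `TRUE`, stop after the graph-attention layer and
#'   return the `g x e` spot embedding `E3` (the pretrained-encoder mode
#'   used by the gene expression predictor); otherwise return the `g x p`
#'   expression prediction.
#' @return A numeric matrix (`g x e` or `g x p`).
#' @export
seg_forward <- function(patches, adj, state, detach_head = FALSE) {
  E1 <- cnn_encode(patches, state)
  E2 <- intermediate_fc(E1, state)
  E3 <- gat_forward(E2, adj, state)
  if (detach_head) return(E3)
  expression_head(E3, state)
}

#' Mean-squared-error training loss of the SEG
#'
#' Mean of squared entrywise differences between predicted and true spot
#' expression (the squared-norm objective averaged over all `g * p` entries,
#' so the scale does not depend on spot or gene counts).
#'
#' @param pred,truth `g x p` matrices.
#' @return Scalar loss.
#' @export
seg_loss <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  mean((pred - truth)^2)
}

# --- backward pass ---------------------------------------------------------

# Full-sample forward keeping every cache needed for the gradient.
seg_forward_train <- function(patches, adj, truth, state) {
  cfg <- state$cfg
  cnn <- seg_cnn_forward(patches, state, keep_cache = TRUE)
  E2pre <- linear_forward(cnn$E1, state$params$fc1)
  E2 <- relu(E2pre)
  gat <- seg_gat_forward(E2, adj, state, keep_cache = TRUE)
  A1pre <- linear_forward(gat$E3, state$params$head1)
  A1 <- relu(A1pre)
  Y <- linear_forward(A1, state$params$head2)
  loss <- mean((Y - truth)^2)
  list(loss = loss, Y = Y,
       cache = list(cnn = cnn, E2pre = E2pre, E2 = E2, gat = gat,
                    A1pre = A1pre, A1 = A1, adj = adj))
}

seg_backward <- function(fw, truth, state) {
  cfg <- state$cfg
  p <- state$params
  ch <- fw$cache
  g <- nrow(fw$Y)
  e_a <- cfg$embed_attn
  grads <- tree_map(function(x) x * 0, p)

  dY <- 2 * (fw$Y - truth) / length(truth)
  lb <- linear_backward(dY, ch$A1, p$head2)
  grads$head2$W <- lb$dW; grads$head2$b <- lb$db
  dA1 <- relu_grad(lb$dX, ch$A1pre)
  lb <- linear_backward(dA1, ch$gat$E3, p$head1)
  grads$head1$W <- lb$dW; grads$head1$b <- lb$db
  dE3 <- lb$dX

  E2 <- ch$E2
  support <- ch$gat$cache$support
  dE2 <- matrix(0, nrow(E2), ncol(E2))
  for (l in seq_len(cfg$n_heads)) {
    hc <- ch$gat$cache$heads[[l]]
    hd <- p$heads[[l]]
    cols <- ((l - 1L) * e_a + 1L):(l * e_a)
    dH <- dE3[, cols, drop = FALSE]
    dpre <- head_f_grad(dH, hc$pre, cfg$head_nonlinearity)

    dP <- hc$alpha_s * dpre
    dQ <- t(hc$An) %*% dpre
    dAn <- dpre %*% t(hc$Q)
    dAn[!support] <- 0
    dalpha_s <- rowSums(dpre * hc$P)

    vm <- head_value_mats(hd, cfg)
    dWv_s <- t(dP) %*% E2
    dWv_n <- t(dQ) %*% E2
    dE2 <- dE2 + dP %*% vm$Wv_s + dQ %*% vm$Wv_n

    # softmax backward over each neighbor set
    srs <- rowSums(hc$An * dAn)
    dR <- hc$An * sweep(dAn, 1L, srs, "-")
    if (cfg$alpha_mode == "pre_softmax") {
      # alpha_s = 1 / (1 + sum_k relu(z)_jk over neighbors)
      dSraw <- -hc$alpha_s^2 * dalpha_s
      add <- matrix(dSraw, g, g)     # add[j, k] = dSraw[j]
      add[!support] <- 0
      dR <- dR + add
    }
    dZ <- dR * (hc$sc$z > 0)
    du <- rowSums(dZ)
    dw <- colSums(dZ)

    da_s <- drop(t(hc$sc$S_s) %*% du)
    da_n <- drop(t(hc$sc$S_n) %*% dw)
    dS_s <- outer(du, hd$a_s)
    dS_n <- outer(dw, hd$a_n)
    dW_s <- t(dS_s) %*% E2
    dW_n <- t(dS_n) %*% E2
    dE2 <- dE2 + dS_s %*% hd$W_s + dS_n %*% hd$W_n

    grads$heads[[l]]$a_s <- da_s
    grads$heads[[l]]$a_n <- da_n
    if (cfg$tie_value_weights) {
      grads$heads[[l]]$W_s <- dW_s + dWv_s
      grads$heads[[l]]$W_n <- dW_n + dWv_n
    } else {
      grads$heads[[l]]$W_s <- dW_s
      grads$heads[[l]]$W_n <- dW_n
      grads$heads[[l]]$Wv_s <- dWv_s
      grads$heads[[l]]$Wv_n <- dWv_n
    }
  }

  dE2 <- relu_grad(dE2, ch$E2pre)
  lb <- linear_backward(dE2, ch$cnn$E1, p$fc1)
  grads$fc1$W <- lb$dW; grads$fc1$b <- lb$db
  dE1 <- relu_grad(lb$dX, ch$cnn$cache$E1pre)
  lb <- linear_backward(dE1, ch$cnn$cache$flat, p$proj)
  grads$proj$W <- lb$dW; grads$proj$b <- lb$db

  dX <- array(t(lb$dX), c(cfg$final_side, cfg$final_side,
                          cfg$conv_channels[length(cfg$conv_channels)], g))
  for (b in rev(seq_along(p$conv))) {
    blk <- ch$cnn$cache$blocks[[b]]
    if (cfg$pool[b]) dX <- maxpool_backward(dX, blk$pool)
    dX <- relu_grad(dX, blk$pre)
    cb <- conv_backward(dX, blk$conv)
    grads$conv[[b]]$W <- cb$dW
    grads$conv[[b]]$b <- cb$db
    dX <- cb$dX
  }
  grads
}

#' Train the spot embedding generator
#'
#' Optimizes all SEG parameters with Adam against the mean-squared-error
#' loss between predicted and true spot expression, one full-sample step per
#' sample per epoch (the convolutional front end sees each sample's spots as
#' one batch; the attention layer always runs on the full per-sample graph).
#' Seeded and reproducible: the same seed, config and inputs give an
#' identical state.
#'
#' @param samples List of samples, each a list with `patches`
#'   (`side x side x 3 x g`, 0--255; resized internally to
#'   `cfg$patch_side`), `adj` (binary adjacency) and `expr` (`g x p` matrix,
#'   columns named by gene; all samples must share the same gene set/order).
#' @param cfg A [seg_config()].
#' @param verbose Print the mean training loss every 20 epochs.
#' @return Trained `seg_state` (with `$gene_ids` and `$loss_history`).
#' @export
train_seg <- function(samples, cfg, verbose = FALSE) {
  stopifnot(length(samples) >= 1L)
  gene_ids <- colnames(samples[[1L]]$expr)
  for (s in samples) {
    if (!identical(colnames(s$expr), gene_ids)) {
      stop("all samples must share the same gene set (identical gene order)")
    }
    stopifnot(ncol(s$expr) == cfg$n_genes)
  }
  set.seed(cfg$seed)
  state <- seg_init(cfg)
  state$gene_ids <- gene_ids
  prepped <- lapply(samples, function(s) {
    list(patches = resize_stack(s$patches, cfg$patch_side),
         adj = s$adj, expr = s$expr)
  })
  opt <- adam_init(state$params)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    losses <- numeric(length(prepped))
    for (i in seq_along(prepped)) {
      s <- prepped[[i]]
      fw <- seg_forward_train(s$patches, s$adj, s$expr, state)
      grads <- seg_backward(fw, s$expr, state)
      upd <- adam_step(state$params, grads, opt, lr = cfg$learning_rate)
      state$params <- upd$params
      opt <- upd$opt
      losses[i] <- fw$loss
    }
    history[epoch] <- mean(losses)
    if (verbose && (epoch %% 20L == 0L || epoch == 1L)) {
      message(sprintf("epoch %d: loss %.5f", epoch, history[epoch]))
    }
  }
  state$loss_history <- history
  state
}

#' Spot embeddings from a trained SEG (detached expression head)
#'
#' @inheritParams seg_forward
#' @return `g x e` embedding matrix `E3`.
#' @export
seg_embed <- function(patches, adj, state) {
  patches <- resize_stack(patches, state$cfg$patch_side)
  seg_forward(patches, adj, state, detach_head = TRUE)
}
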