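# Minimal neural-network core used by the three model modules.
#
# Layout conventions:
#   image batch  : numeric array (H, W, C, N), channels-last, N samples
#   feature batch: numeric matrix (N, d)
#   conv weights : array (k, k, C_in, C_out), stride 1, 'same' zero padding,
#                  k odd; flattened column order (dy, dx, channel) matches the
#                  im2col gather below
# Forward passes return caches with everything the matching backward pass
# needs; gradients are exact (verified against finite differences in the
# test suite). All heavy lifting is a gather + one BLAS matmul per layer.

conv_init <- function(k, c_in, c_out) {
  list(W = array(stats::rnorm(k * k * c_in * c_out,
                              sd = sqrt(2 / (k * k * c_in))),
                 c(k, k, c_in, c_out)),
       b = numeric(c_out))
}

linear_init <- function(d_in, d_out, sd = sqrt(2 / d_in)) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = numeric(d_out))
}

# im2col gather indices for an H x W x C input padded by p on each border.
im2col_index <- function(H, W, C, k) {
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  pos0 <- i + (j - 1L) * Hp                      # (i, j) in padded volume
  di <- rep(0:(k - 1L), times = k * C)
  dj <- rep(rep(0:(k - 1L), each = k), times = C)
  ch <- rep(seq_len(C), each = k * k)
  offs <- di + dj * Hp + (ch - 1L) * Hp * Wp
  rep(pos0, times = length(offs)) + rep(offs, each = length(pos0))
}

conv_forward <- function(X, layer) {
  d <- dim(X); H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  k <- dim(layer$W)[1L]
  p <- (k - 1L) %/% 2L
  c_out <- dim(layer$W)[4L]
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Xp <- array(0, c(Hp, Wp, C, N))
  Xp[(p + 1L):(p + H), (p + 1L):(p + W), , ] <- X
  dim(Xp) <- c(Hp * Wp * C, N)
  idx <- im2col_index(H, W, C, k)
  G <- Xp[idx, , drop = FALSE]                   # (HW * k2C) x N
  k2C <- k * k * C; HW <- H * W
  Gm <- matrix(aperm(array(G, c(HW, k2C, N)), c(1L, 3L, 2L)), HW * N, k2C)
  Wm <- matrix(layer$W, k2C, c_out)
  out <- Gm %*% Wm
  out <- sweep(out, 2L, layer$b, "+")
  out <- aperm(array(out, c(HW, N, c_out)), c(1L, 3L, 2L))
  dim(out) <- c(H, W, c_out, N)
  list(out = out,
       cache = list(Gm = Gm, idx = idx, dims = d, k = k, p = p,
                    c_out = c_out, Wm = Wm))
}

conv_backward <- function(dOut, cache) {
  d <- cache$dims; H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  k <- cache$k; p <- cache$p; c_out <- cache$c_out
  HW <- H * W; k2C <- k * k * C
  Hp <- H + 2L * p; Wp <- W + 2L * p
  dim(dOut) <- c(HW, c_out, N)
  Dm <- matrix(aperm(dOut, c(1L, 3L, 2L)), HW * N, c_out)
  dW <- crossprod(cache$Gm, Dm)
  db <- colSums(Dm)
  dGm <- Dm %*% t(cache$Wm)                      # (HW * N) x k2C
  dG <- matrix(aperm(array(dGm, c(HW, N, k2C)), c(1L, 3L, 2L)), HW * k2C, N)
  rs <- rowsum(dG, group = cache$idx)            # scatter-add (col2im)
  dXp <- matrix(0, Hp * Wp * C, N)
  dXp[as.integer(rownames(rs)), ] <- rs
  dim(dXp) <- c(Hp, Wp, C, N)
  dX <- dXp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
  list(dX = dX, dW = array(dW, c(k, k, C, c_out)), db = db)
}

# 2x2 max-pool, stride 2; ties resolved to the first window element in the
# fixed order (top-left, bottom-left, top-right, bottom-right).
maxpool_forward <- function(X) {
  d <- dim(X)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
    stop("maxpool requires even spatial dimensions, got ", d[1L], " x ", d[2L])
  }
  ro <- seq(1L, d[1L], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2L], by = 2L); ce <- co + 1L
  parts <- list(X[ro, co, , , drop = FALSE], X[re, co, , , drop = FALSE],
                X[ro, ce, , , drop = FALSE], X[re, ce, , , drop = FALSE])
  out <- parts[[1L]]
  arg <- array(1L, dim(out))
  for (kk in 2:4) {
    upd <- parts[[kk]] > out
    out[upd] <- parts[[kk]][upd]
    arg[upd] <- kk
  }
  list(out = out, cache = list(arg = arg, dims = d))
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$dims
  dX <- array(0, d)
  ro <- seq(1L, d[1L], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2L], by = 2L); ce <- co + 1L
  sel <- list(list(ro, co), list(re, co), list(ro, ce), list(re, ce))
  for (kk in 1:4) {
    m <- dOut * (cache$arg == kk)
    dX[sel[[kk]][[1L]], sel[[kk]][[2L]], , ] <-
      dX[sel[[kk]][[1L]], sel[[kk]][[2L]], , , drop = FALSE] + m
  }
  dX
}

relu <- function(x) pmax(x, 0)
relu_grad <- function(dOut, x) dOut * (x > 0)

linear_forward <- function(X, layer) {
  sweep(X %*% layer$W, 2L, layer$b, "+")
}

linear_backward <- function(dOut, X, layer) {
  list(dX = dOut %*% t(layer$W),
       dW = crossprod(X, dOut),
       db = colSums(dOut))
}

# Numerically stable row-wise softmax restricted to `support` (logical matrix
# of the same shape); rows with empty support come back all-zero.
masked_softmax <- function(scores, support) {
  out <- matrix(0, nrow(scores), ncol(scores))
  any_row <- rowSums(support) > 0
  if (any(any_row)) {
    s <- scores
    s[!support] <- -Inf
    m <- apply(s[any_row, , drop = FALSE], 1L, max)
    e <- exp(sweep(s[any_row, , drop = FALSE], 1L, m, "-"))
    e[!support[any_row, , drop = FALSE]] <- 0
    out[any_row, ] <- e / rowSums(e)
  }
  out
}

# --- parameter-tree utilities + Adam ---------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    out
  } else {
    f(a, b)
  }
}

tree_zip3 <- function(f, a, b, c) {
  if (is.list(a)) {
    out <- Map(function(x, y, z) tree_zip3(f, x, y, z), a, b, c)
    out
  } else {
    f(a, b, c)
  }
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  params <- tree_zip3(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, opt$m, opt$v)
  list(params = params, opt = opt)
}
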