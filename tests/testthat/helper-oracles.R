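# Independent brute-force oracles and small fixture builders.
# Every oracle is written as plain loops over the defining formulas, kept
# deliberately separate from the vectorized implementations they check.

ns <- asNamespace("spotgat")

oracle_bilinear <- function(patch, target) {
  s_in <- dim(patch)[1L]
  out <- array(0, c(target, target, 3L))
  coord <- function(i) min(max((i + 0.5) * s_in / target - 0.5, 0), s_in - 1)
  for (i in 0:(target - 1)) {
    for (j in 0:(target - 1)) {
      sy <- coord(i); sx <- coord(j)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, s_in - 1); x1 <- min(x0 + 1, s_in - 1)
      wy <- sy - y0; wx <- sx - x0
      for (ch in 1:3) {
        out[i + 1, j + 1, ch] <-
          (1 - wy) * (1 - wx) * patch[y0 + 1, x0 + 1, ch] +
          (1 - wy) * wx       * patch[y0 + 1, x1 + 1, ch] +
          wy       * (1 - wx) * patch[y1 + 1, x0 + 1, ch] +
          wy       * wx       * patch[y1 + 1, x1 + 1, ch]
      }
    }
  }
  out
}

oracle_distances <- function(spots) {
  g <- nrow(spots)
  d <- matrix(0, g, g)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      d[i, j] <- sqrt((spots$x[i] - spots$x[j])^2 +
                      (spots$y[i] - spots$y[j])^2)
    }
  }
  d
}

oracle_adjacency <- function(spots, threshold) {
  d <- oracle_distances(spots)
  g <- nrow(d)
  adj <- matrix(0, g, g)
  for (i in seq_len(g)) {
    mx <- max(d[i, ])
    for (j in seq_len(g)) {
      if (i != j && mx > 0 && d[i, j] / mx < threshold) adj[i, j] <- 1
    }
  }
  adj
}

# direct convolution (3x3, stride 1, zero 'same' padding) on one image
oracle_conv <- function(X, W, b) {
  H <- dim(X)[1L]; Wd <- dim(X)[2L]; C <- dim(X)[3L]
  k <- dim(W)[1L]; co <- dim(W)[4L]
  p <- (k - 1) %/% 2
  out <- array(0, c(H, Wd, co))
  for (oc in seq_len(co)) {
    for (i in seq_len(H)) {
      for (j in seq_len(Wd)) {
        acc <- b[oc]
        for (di in seq_len(k)) {
          for (dj in seq_len(k)) {
            ii <- i + di - 1 - p; jj <- j + dj - 1 - p
            if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
              for (ic in seq_len(C)) {
                acc <- acc + X[ii, jj, ic] * W[di, dj, ic, oc]
              }
            }
          }
        }
        out[i, j, oc] <- acc
      }
    }
  }
  out
}

# minimal attention-layer state with arbitrary dimensions (no CNN part)
make_gat_state <- function(e_c, e_a, h, f = "relu", mode = "post_softmax") {
  heads <- lapply(seq_len(h), function(l) {
    list(a_s = rnorm(e_a), a_n = rnorm(e_a),
         W_s = matrix(rnorm(e_a * e_c), e_a, e_c),
         W_n = matrix(rnorm(e_a * e_c), e_a, e_c),
         Wv_s = matrix(rnorm(e_a * e_c), e_a, e_c),
         Wv_n = matrix(rnorm(e_a * e_c), e_a, e_c))
  })
  structure(list(cfg = list(n_heads = h, embed_attn = e_a,
                            head_nonlinearity = f, alpha_mode = mode,
                            tie_value_weights = FALSE),
                 params = list(heads = heads)),
            class = "seg_state")
}

# per-edge loop oracle for attention coefficients and head outputs
oracle_gat <- function(E2, adj, state) {
  cfg <- state$cfg
  g <- nrow(E2)
  fct <- if (cfg$head_nonlinearity == "relu") {
    function(x) pmax(x, 0)
  } else {
    function(x) ifelse(x > 0, x, exp(x) - 1)
  }
  cols <- NULL
  for (l in seq_len(cfg$n_heads)) {
    hd <- state$params$heads[[l]]
    e_a <- cfg$embed_attn
    out <- matrix(0, g, e_a)
    for (j in seq_len(g)) {
      nbr <- which(adj[j, ] == 1)
      z <- numeric(length(nbr))
      for (t in seq_along(nbr)) {
        k <- nbr[t]
        z[t] <- max(0, sum(hd$a_s * (hd$W_s %*% E2[j, ])) +
                       sum(hd$a_n * (hd$W_n %*% E2[k, ])))
      }
      if (length(nbr) > 0) {
        e <- exp(z - max(z))
        an <- e / sum(e)
        a_s <- 1 / (1 + sum(an))
      } else {
        an <- numeric(0)
        a_s <- 1
      }
      acc <- a_s * (hd$Wv_s %*% E2[j, ])
      for (t in seq_along(nbr)) {
        acc <- acc + an[t] * (hd$Wv_n %*% E2[nbr[t], ])
      }
      out[j, ] <- fct(as.vector(acc))
    }
    cols <- cbind(cols, out)
  }
  cols
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

oracle_youden <- function(probs, labels) {
  # exhaustive scan maximizing J = sens + spec - 1; counts kept as integers
  # so ties are exact and the smallest tied threshold wins
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  best_score <- -Inf; best_t <- Inf
  for (t in sort(unique(probs))) {
    tp <- sum(probs[labels == 1] >= t)
    tn <- sum(probs[labels == 0] < t)
    score <- tp * nneg + tn * npos
    if (score > best_score) { best_score <- score; best_t <- t }
  }
  best_t
}

# gradient checking: flatten/unflatten a parameter tree preserving dims
tree_flatten <- function(a) unlist(a, use.names = FALSE)
tree_unflatten <- function(v, skel) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  walk(skel)
}

max_grad_mismatch <- function(loss_fn, params, grads, n_check = 50,
                              eps = 1e-6, seed = 7) {
  set.seed(seed)
  fl <- tree_flatten(params); gfl <- tree_flatten(grads)
  idxs <- sort(sample(length(fl), min(n_check, length(fl))))
  maxrel <- 0
  for (i in idxs) {
    vp <- fl; vp[i] <- vp[i] + eps
    vm <- fl; vm[i] <- vm[i] - eps
    ng <- (loss_fn(tree_unflatten(vp, params)) -
           loss_fn(tree_unflatten(vm, params))) / (2 * eps)
    denom <- max(1e-4, abs(ng), abs(gfl[i]))
    maxrel <- max(maxrel, abs(ng - gfl[i]) / denom)
  }
  maxrel
}

grid_spots <- function(nr, nc, spacing = 1L, origin = 0L) {
  gr <- expand.grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  data.frame(spot_id = sprintf("s%03d", seq_len(nr * nc)),
             x = origin + gr$col * spacing,
             y = origin + gr$row * spacing,
             stringsAsFactors = FALSE)
}

const_image <- function(side, value = 255) {
  array(value, c(side, side, 3L))
}
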