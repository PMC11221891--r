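tiny_seg <- function(n_genes = 3, e_c = 6, e_a = 4, h = 2, seed = 42,
                     ...) {
  cfg <- seg_config(n_genes = n_genes, patch_side = 8L,
                    conv_channels = c(4L, 5L), pool = c(TRUE, TRUE),
                    embed_cnn = e_c, embed_attn = e_a, n_heads = h,
                    head_hidden = 5L, epochs = 1L, seed = seed, ...)
  set.seed(seed)
  ns$seg_init(cfg)
}

line_spots <- function(xs) {
  data.frame(spot_id = sprintf("s%d", seq_along(xs)), x = xs,
             y = rep(0L, length(xs)))
}

test_that("cnn_encode is zero on zero input, per-spot independent, and matches the conv oracle", {
  st <- tiny_seg()
  zero <- array(0, c(8, 8, 3, 4))
  expect_equal(max(abs(cnn_encode(zero, st))), 0)   # zero biases at init

  set.seed(1)
  patches <- array(runif(8 * 8 * 3 * 5, 0, 255), c(8, 8, 3, 5))
  E1 <- cnn_encode(patches, st)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(cnn_encode(patches[, , , perm], st), E1[perm, ])

  # one-block reduced config against the hand-rolled convolution oracle
  cfg1 <- seg_config(n_genes = 1, patch_side = 8L, conv_channels = 4L,
                     pool = TRUE, embed_cnn = 5L, embed_attn = 2L,
                     n_heads = 1L, head_hidden = 3L)
  set.seed(2)
  st1 <- ns$seg_init(cfg1)
  x <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3, 1))
  conv <- oracle_conv(x[, , , 1] / 255, st1$params$conv[[1]]$W,
                      st1$params$conv[[1]]$b)
  act <- pmax(conv, 0)
  pooled <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (ch in 1:4) {
    pooled[i, j, ch] <- max(act[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch])
  }
  flat <- matrix(as.vector(pooled), 1)
  expected <- pmax(flat %*% st1$params$proj$W +
                     matrix(st1$params$proj$b, 1), 0)
  expect_equal(cnn_encode(x, st1), expected, tolerance = 1e-10)

  expect_error(cnn_encode(array(0, c(7, 7, 3, 1)), st), "must be 8 x 8")
})

test_that("intermediate_fc is a row-wise affine map with ReLU", {
  st <- tiny_seg(e_c = 4)
  E1 <- matrix(abs(rnorm(12)), 3, 4)
  st$params$fc1$W <- diag(4); st$params$fc1$b <- rep(0, 4)
  expect_equal(intermediate_fc(E1, st), E1)

  st$params$fc1$W <- matrix(0, 4, 4); st$params$fc1$b <- c(-1, 0, 2, 3)
  out <- intermediate_fc(E1, st)
  for (i in 1:3) expect_equal(out[i, ], c(0, 0, 2, 3))

  set.seed(6)
  st$params$fc1$W <- matrix(rnorm(16), 4, 4)
  st$params$fc1$b <- rnorm(4)
  manual <- pmax(E1 %*% st$params$fc1$W +
                   matrix(st$params$fc1$b, 3, 4, byrow = TRUE), 0)
  expect_equal(intermediate_fc(E1, st), manual)
})

test_that("attention coefficients: softmax rows sum to 1, alpha_s is 1/2 or 1", {
  set.seed(7)
  st <- make_gat_state(e_c = 5, e_a = 3, h = 1)
  E2 <- matrix(rnorm(20), 4, 5)
  adj <- rbind(c(0, 1, 1, 0), c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 0))
  ac <- attention_coefficients(E2, adj, st, head = 1)
  expect_equal(rowSums(ac$alpha_n), c(1, 1, 1, 0))
  expect_identical(ac$alpha_s, c(0.5, 0.5, 0.5, 1))
  expect_true(all(ac$alpha_n[adj == 0] == 0))
})

test_that("gat_forward: self-only identity, head concatenation, loop oracle, equivariance", {
  set.seed(8)
  # empty adjacency + identity value matrix returns truncated self features
  st <- make_gat_state(e_c = 5, e_a = 3, h = 1)
  st$params$heads[[1]]$Wv_s <- cbind(diag(3), matrix(0, 3, 2))
  E2 <- matrix(abs(rnorm(20)), 4, 5)
  adj0 <- matrix(0, 4, 4)
  expect_equal(gat_forward(E2, adj0, st), E2[, 1:3])

  # h = 2 equals the column-concatenation of two single-head runs
  st2 <- make_gat_state(e_c = 5, e_a = 3, h = 2)
  adj <- oracle_adjacency(line_spots(c(0L, 1L, 2L, 6L)), 0.5)
  full <- gat_forward(E2, adj, st2)
  for (l in 1:2) {
    st1 <- st2
    st1$cfg$n_heads <- 1L
    st1$params$heads <- st2$params$heads[l]
    expect_equal(gat_forward(E2, adj, st1), full[, (3 * l - 2):(3 * l)])
  }

  # dense random instance against the per-edge loop oracle
  g <- 6
  E2b <- matrix(rnorm(g * 5), g, 5)
  adjb <- matrix(rbinom(g * g, 1, 0.5), g, g); diag(adjb) <- 0
  expect_equal(gat_forward(E2b, adjb, st2), oracle_gat(E2b, adjb, st2),
               tolerance = 1e-10)

  # permutation equivariance
  perm <- sample(g)
  expect_equal(gat_forward(E2b[perm, ], adjb[perm, perm], st2),
               gat_forward(E2b, adjb, st2)[perm, ])
})

test_that("expression head: zero map, scalar regression oracle, detached path", {
  st <- tiny_seg(n_genes = 1)
  E3 <- matrix(0, 4, 8)
  expect_equal(max(abs(expression_head(E3, st))), 0)  # zero biases at init

  set.seed(9)
  E3 <- matrix(rnorm(32), 4, 8)
  h <- pmax(E3 %*% st$params$head1$W +
              matrix(st$params$head1$b, 4, 5, byrow = TRUE), 0)
  expected <- h %*% st$params$head2$W + st$params$head2$b
  expect_equal(expression_head(E3, st), expected)

  # detaching the head returns the attention-layer embedding unchanged
  patches <- array(runif(8 * 8 * 3 * 3, 0, 255), c(8, 8, 3, 3))
  adj <- oracle_adjacency(line_spots(c(0L, 1L, 5L)), 0.5)
  E2 <- intermediate_fc(cnn_encode(patches, st), st)
  expect_equal(seg_forward(patches, adj, st, detach_head = TRUE),
               gat_forward(E2, adj, st))
})

test_that("seg_loss is the mean squared entrywise error", {
  set.seed(10)
  a <- matrix(rnorm(12), 3, 4)
  expect_equal(seg_loss(a, a), 0)
  expect_equal(seg_loss(a + 1, a), 1)
  b <- matrix(rnorm(12), 3, 4)
  expect_equal(seg_loss(a, b), sum((a - b)^2) / 12)
})

test_that("the full SEG gradient matches finite differences", {
  st <- tiny_seg()
  set.seed(12)
  g <- 5
  patches <- array(runif(8 * 8 * 3 * g, 0, 255), c(8, 8, 3, g))
  adj <- oracle_adjacency(line_spots(c(0L, 1L, 2L, 8L, 9L)), 0.4)
  truth <- matrix(rnorm(g * 3), g, 3)
  fw <- ns$seg_forward_train(patches, adj, truth, st)
  gr <- ns$seg_backward(fw, truth, st)
  loss_fn <- function(p) {
    s <- st; s$params <- p
    ns$seg_forward_train(patches, adj, truth, s)$loss
  }
  expect_lt(max_grad_mismatch(loss_fn, st$params, gr, n_check = 60), 1e-5)

  # tied value weights + elu + pre-softmax self-coefficients
  st2 <- tiny_seg(h = 1, seed = 13, head_nonlinearity = "elu",
                  tie_value_weights = TRUE, alpha_mode = "pre_softmax")
  fw2 <- ns$seg_forward_train(patches, adj, truth, st2)
  gr2 <- ns$seg_backward(fw2, truth, st2)
  loss_fn2 <- function(p) {
    s <- st2; s$params <- p
    ns$seg_forward_train(patches, adj, truth, s)$loss
  }
  expect_lt(max_grad_mismatch(loss_fn2, st2$params, gr2, n_check = 60), 1e-5)
})

test_that("training learns a noiseless intensity-to-expression map (>= 10x loss drop)", {
  set.seed(20)
  g <- 16
  vals <- seq(20, 235, length.out = g)
  patches <- array(0, c(8, 8, 3, g))
  for (i in seq_len(g)) patches[, , , i] <- vals[i]
  spots <- grid_spots(4, 4, spacing = 2L)
  adj <- suppressMessages(build_adjacency(spots, threshold = 0.4))
  expr <- cbind(vals / 255, 1 - vals / 255)
  colnames(expr) <- c("gene_1", "gene_2")
  cfg <- seg_config(n_genes = 2, patch_side = 8L, conv_channels = c(4L, 8L),
                    pool = c(TRUE, TRUE), embed_cnn = 16L, embed_attn = 8L,
                    n_heads = 2L, head_hidden = 16L, epochs = 200L, seed = 3L)
  st <- train_seg(list(list(patches = patches, adj = adj, expr = expr)), cfg)
  expect_gte(st$loss_history[1] / tail(st$loss_history, 1), 10)
})

test_that("mismatched gene sets across samples are rejected", {
  cfg <- seg_config(n_genes = 2, patch_side = 8L, conv_channels = 4L,
                    pool = TRUE, embed_cnn = 4L, embed_attn = 2L,
                    n_heads = 1L, head_hidden = 4L, epochs = 1L)
  mk <- function(genes) {
    e <- matrix(1, 2, 2); colnames(e) <- genes
    list(patches = array(0, c(8, 8, 3, 2)), adj = matrix(0, 2, 2), expr = e)
  }
  expect_error(train_seg(list(mk(c("a", "b")), mk(c("a", "c"))), cfg),
               "same gene set")
})
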