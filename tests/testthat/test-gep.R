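tiny_gep <- function(e = 6, p = 4, seed = 5) {
  cfg <- gep_config(embed_dim = e, n_genes = p, bulk_hidden = 5L,
                    decoder_hidden = 7L, epochs = 1L, seed = seed)
  set.seed(seed)
  ns$gep_init(cfg)
}

test_that("encode_bulk: zero map at zero bias, linear pre-activations, matmul oracle", {
  st <- tiny_gep()
  expect_equal(encode_bulk(rep(0, 4), st), rep(0, 6))  # zero biases at init

  set.seed(1)
  bulk <- rnorm(4)
  z <- encode_bulk(bulk, st)
  manual <- pmax(matrix(bulk, 1) %*% st$params$enc1$W +
                   matrix(st$params$enc1$b, 1), 0)
  manual <- drop(manual %*% st$params$enc2$W + st$params$enc2$b)
  expect_equal(z, manual)

  # bias-free layers are homogeneous: doubling the bulk doubles the output
  st0 <- st
  expect_equal(encode_bulk(2 * abs(bulk), st0), 2 * encode_bulk(abs(bulk), st0))
})

test_that("align_and_fuse z-scores both embeddings and broadcasts the bulk", {
  st <- tiny_gep()
  set.seed(2)
  E3 <- matrix(rnorm(5 * 6), 5, 6)
  Z1 <- rnorm(6)
  Z3 <- align_and_fuse(E3, Z1, st)
  expect_equal(dim(Z3), c(6L, 5L))

  # loop oracle: multiply, z-score, add
  E4 <- st$params$W_spots %*% t(E3)
  Z2 <- drop(st$params$W_bulk %*% Z1)
  E5 <- E4
  for (r in 1:6) {
    mu <- mean(E4[r, ]); sd_ <- sqrt(mean((E4[r, ] - mu)^2) + 1e-8)
    E5[r, ] <- (E4[r, ] - mu) / sd_
  }
  z2n <- (Z2 - mean(Z2)) / sqrt(mean((Z2 - mean(Z2))^2) + 1e-8)
  oracle <- E5
  for (cc in 1:5) oracle[, cc] <- E5[, cc] + z2n
  expect_equal(Z3, oracle, tolerance = 1e-12)

  # duplicated spots give identical fused columns
  E3d <- E3[c(1, 1, 2, 3, 4), ]
  Z3d <- align_and_fuse(E3d, Z1, st)
  expect_equal(Z3d[, 1], Z3d[, 2])

  expect_error(align_and_fuse(E3[1, , drop = FALSE], Z1, st), "m = 1")
})

test_that("decode_spots: zero map, scalar oracle, column-permutation equivariance", {
  st <- tiny_gep(p = 1)
  expect_equal(max(abs(decode_spots(matrix(0, 6, 3), st))), 0)

  set.seed(3)
  Z3 <- matrix(rnorm(18), 6, 3)
  X <- t(Z3)
  h1 <- pmax(X %*% st$params$dec1$W + matrix(st$params$dec1$b, 3, 7, byrow = TRUE), 0)
  h2 <- pmax(h1 %*% st$params$dec2$W + matrix(st$params$dec2$b, 3, 7, byrow = TRUE), 0)
  expected <- h2 %*% st$params$dec3$W + st$params$dec3$b
  expect_equal(decode_spots(Z3, st), expected)

  perm <- c(3, 1, 2)
  expect_equal(decode_spots(Z3[, perm], st),
               decode_spots(Z3, st)[perm, , drop = FALSE])
})

test_that("gep_loss compares the spot-average to the bulk vector", {
  bulk <- c(1, 2, 3)
  pred <- rbind(bulk, bulk, bulk)
  expect_equal(gep_loss(pred, bulk), 0)
  off <- rbind(bulk + 5, bulk - 5)
  expect_equal(gep_loss(off, bulk), 0)     # symmetric offsets cancel
  set.seed(4)
  Y <- matrix(rnorm(15), 3, 5); b <- rnorm(5)
  expect_equal(gep_loss(Y, b), mean((colMeans(Y) - b)^2))
})

test_that("the GEP gradient matches finite differences", {
  st <- tiny_gep()
  set.seed(5)
  E3 <- matrix(rnorm(5 * 6), 5, 6)
  bulk <- rnorm(4)
  fw <- ns$gep_forward_train(E3, bulk, st)
  gr <- ns$gep_backward(fw, bulk, E3, st)
  loss_fn <- function(p) {
    s <- st; s$params <- p
    ns$gep_forward_train(E3, bulk, s)$loss
  }
  expect_lt(max_grad_mismatch(loss_fn, st$params, gr, n_check = 80), 1e-5)
})

test_that("train_gep freezes the SEG and rejects incompatible dimensions", {
  cfg <- seg_config(n_genes = 3, patch_side = 8L, conv_channels = 4L,
                    pool = TRUE, embed_cnn = 6L, embed_attn = 4L,
                    n_heads = 2L, head_hidden = 5L, epochs = 2L, seed = 1L)
  set.seed(1)
  g <- 4
  patches <- array(runif(8 * 8 * 3 * g, 0, 255), c(8, 8, 3, g))
  spots <- grid_spots(2, 2, spacing = 3L)
  adj <- suppressMessages(build_adjacency(spots, threshold = 0.9))
  expr <- matrix(abs(rnorm(g * 3)), g, 3,
                 dimnames = list(NULL, c("g1", "g2", "g3")))
  seg <- train_seg(list(list(patches = patches, adj = adj, expr = expr)), cfg)
  before <- serialize(seg$params, NULL)

  gcfg <- gep_config(embed_dim = 8L, n_genes = 3L, bulk_hidden = 4L,
                     decoder_hidden = 4L, epochs = 3L, seed = 2L)
  bulk <- c(g1 = 1, g2 = 2, g3 = 0.5)
  gep <- train_gep(list(list(patches = patches, adj = adj, bulk = bulk)),
                   seg, gcfg)
  expect_identical(serialize(seg$params, NULL), before)   # frozen encoder
  expect_s3_class(gep, "gep_state")
  expect_length(gep$loss_history, 3L)

  bad <- gep_config(embed_dim = 5L, n_genes = 3L)
  expect_error(train_gep(list(list(patches = patches, adj = adj, bulk = bulk)),
                         seg, bad), "does not match")
  badbulk <- c(g1 = 1, zz = 2, g3 = 0.5)
  expect_error(train_gep(list(list(patches = patches, adj = adj,
                                   bulk = badbulk)), seg, gcfg),
               "gene set")
})
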