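test_that("slp_forward emits valid tumor probabilities", {
  cfg <- slp_config(patch_side = 16L, conv_channels = c(4L, 6L),
                    fc_hidden = 8L, epochs = 1L)
  set.seed(1)
  st <- ns$slp_init(cfg)
  patches <- array(runif(16 * 16 * 3 * 5, 0, 255), c(16, 16, 3, 5))
  pr <- slp_forward(patches, st)
  expect_true(all(pr >= 0 & pr <= 1))
  # identical patches get identical probabilities
  same <- patches
  same[, , , 2] <- same[, , , 1]
  pr2 <- slp_forward(same, st)
  expect_equal(pr2[1], pr2[2])
  # two-class softmax sums to one
  full <- ns$slp_forward_cache(patches, st)$probs
  expect_equal(rowSums(full), rep(1, 5))
  # tiny-config forward oracle: conv+pool via loops, FCs by hand
  x1 <- patches[, , , 1, drop = FALSE]
  conv <- oracle_conv(x1[, , , 1] / 255, st$params$conv[[1]]$W,
                      st$params$conv[[1]]$b)
  a <- pmax(conv, 0)
  pool1 <- array(0, c(8, 8, 4))
  for (i in 1:8) for (j in 1:8) for (ch in 1:4) {
    pool1[i, j, ch] <- max(a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch])
  }
  conv2 <- oracle_conv(pool1, st$params$conv[[2]]$W, st$params$conv[[2]]$b)
  a2 <- pmax(conv2, 0)
  pool2 <- array(0, c(4, 4, 6))
  for (i in 1:4) for (j in 1:4) for (ch in 1:6) {
    pool2[i, j, ch] <- max(a2[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch])
  }
  pool3 <- array(0, c(2, 2, 6))
  for (i in 1:2) for (j in 1:2) for (ch in 1:6) {
    pool3[i, j, ch] <- max(pool2[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch])
  }
  flat <- matrix(as.vector(pool3), 1)
  h1 <- pmax(flat %*% st$params$fc1$W + matrix(st$params$fc1$b, 1), 0)
  logits <- drop(h1 %*% st$params$fc2$W + st$params$fc2$b)
  expect_equal(unname(pr[1]), exp(logits[2]) / sum(exp(logits)),
               tolerance = 1e-10)
})

test_that("the SLP cross-entropy gradient matches finite differences", {
  cfg <- slp_config(patch_side = 16L, conv_channels = c(4L, 5L),
                    fc_hidden = 6L, epochs = 1L)
  set.seed(2)
  st <- ns$slp_init(cfg)
  patches <- array(runif(16 * 16 * 3 * 6, 0, 255), c(16, 16, 3, 6))
  y <- c(0, 1, 0, 1, 1, 0)
  fw <- ns$slp_forward_cache(patches, st, keep_cache = TRUE)
  gr <- ns$slp_backward(fw, y, st)
  ce <- function(probs) -mean(log(ifelse(y == 1, probs[, 2], probs[, 1])))
  loss_fn <- function(p) {
    s <- st; s$params <- p
    ce(ns$slp_forward_cache(patches, s)$probs)
  }
  expect_lt(max_grad_mismatch(loss_fn, st$params, gr, n_check = 50), 1e-5)
})

test_that("youden_threshold maximizes J over observed probabilities", {
  expect_equal(youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.8)
  # perfectly inverted scores: the best achievable J is <= 0
  probs <- c(0.9, 0.8, 0.1, 0.2)
  labels <- c(0, 0, 1, 1)
  thr <- youden_threshold(probs, labels)
  sens <- mean(probs[labels == 1] >= thr)
  spec <- mean(probs[labels == 0] < thr)
  expect_lte(sens + spec - 1, 0)
  # all probabilities equal: single candidate with J = 0
  expect_equal(youden_threshold(rep(0.4, 6), c(0, 1, 0, 1, 1, 0)), 0.4)
  expect_error(youden_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("youden_threshold equals the exhaustive scan on random instances", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    probs <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(youden_threshold(probs, labels), oracle_youden(probs, labels))
  }
})

test_that("J and the selected threshold are invariant to duplicating negatives", {
  set.seed(4)
  probs <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  dup <- c(probs, probs[labels == 0])
  dlab <- c(labels, labels[labels == 0])
  expect_equal(youden_threshold(probs, labels), youden_threshold(dup, dlab))
})

test_that("classification, F1 and the tumor average behave per contract", {
  probs <- c(0.1, 0.5, 0.9)
  expect_equal(classify_spots(probs, 0), c(1L, 1L, 1L))
  expect_equal(classify_spots(probs, 0.91), c(0L, 0L, 0L))
  expect_equal(classify_spots(probs, 0.5), c(0L, 1L, 1L))

  expect_equal(f1_score(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(f1_score(c(0, 0, 0), c(1, 0, 1)), 0)
  # TP = 3, FP = 1, FN = 2 -> F1 = 2/3
  pred <- c(1, 1, 1, 1, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 1, 1, 0)
  expect_equal(f1_score(pred, truth), 2 / 3)

  expr <- matrix(1:12, 4, 3)
  expect_equal(tumor_average_expression(expr, c(1, 1, 1, 1)), colMeans(expr))
  expect_equal(tumor_average_expression(expr, c(0, 1, 0, 0)), expr[2, ])
  set.seed(5)
  mask <- c(1, 0, 1, 0)
  expect_equal(tumor_average_expression(expr, mask),
               colMeans(expr[c(1, 3), ]))
  expect_error(tumor_average_expression(expr, c(0, 0, 0, 0)), "no tumor")
})

test_that("a short training run separates dark tumor patches from light ones", {
  mk <- function(n, labels, seed) {
    set.seed(seed)
    patches <- array(0, c(16, 16, 3, n))
    for (i in seq_len(n)) {
      base <- if (labels[i] == 1L) 120 else 210
      patches[, , , i] <- pmin(pmax(base + rnorm(16 * 16 * 3, sd = 10), 0), 255)
    }
    patches
  }
  n <- 80
  labels <- rep(c(1L, 0L), n / 2)
  patches <- mk(n, labels, 6)
  cfg <- slp_config(patch_side = 16L, conv_channels = c(4L, 6L),
                    fc_hidden = 8L, epochs = 15L, seed = 7L)
  st <- train_slp(list(list(patches = patches, labels = labels)), cfg,
                  batch_size = 16L)
  test_labels <- rep(c(1L, 0L), 10)
  test_patches <- mk(20, test_labels, 99)
  pr <- slp_forward(test_patches, st)
  expect_gte(auroc(pr, test_labels), 0.95)
})
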