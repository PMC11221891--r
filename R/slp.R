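#' Configuration for the spot label predictor (SLP)
#'
#' A convolutional classifier of spot patches into tumor / non-tumor:
#' convolutional blocks (conv + ReLU + 2x2 max-pool), a final 2x2 max-pool,
#' two fully connected layers and a two-class softmax. The decision
#' threshold on the tumor-class probability is selected on a held-out
#' validation split by Youden's index and persisted with the state.
#'
#' @param patch_side Input patch side (default 224; patches are resized).
#' @param conv_channels Channels per block (default
#'   `c(32, 64, 64, 128, 128)`, five blocks).
#' @param fc_hidden Hidden width of the first FC layer (default 128).
#' @param val_fraction Stratified validation fraction used for threshold and
#'   epoch selection (default 0.2).
#' @param learning_rate,epochs,seed Optimization settings (Adam,
#'   cross-entropy loss).
#' @return An `slp_config` list.
#' @export
slp_config <- function(patch_side = 224L,
                       conv_channels = c(32L, 64L, 64L, 128L, 128L),
                       fc_hidden = 128L,
                       val_fraction = 0.2,
                       learning_rate = 1e-3,
                       epochs = 30L,
                       seed = 1L) {
  nb <- length(conv_channels)
  side <- patch_side
  for (b in seq_len(nb + 1L)) {                   # blocks + final max-pool
    if (side %% 2L != 0L) {
      stop("patch_side ", patch_side, " incompatible with ", nb,
           " pooling blocks plus a final max-pool")
    }
    side <- side %/% 2L
  }
  structure(list(patch_side = as.integer(patch_side),
                 conv_channels = as.integer(conv_channels),
                 fc_hidden = as.integer(fc_hidden),
                 val_fraction = val_fraction,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 final_side = side,
                 flat_dim = side * side * conv_channels[nb]),
            class = "slp_config")
}

slp_init <- function(cfg) {
  stopifnot(inherits(cfg, "slp_config"))
  c_in <- 3L
  conv <- list()
  for (b in seq_along(cfg$conv_channels)) {
    conv[[b]] <- conv_init(3L, c_in, cfg$conv_channels[b])
    c_in <- cfg$conv_channels[b]
  }
  params <- list(conv = conv,
                 fc1 = linear_init(cfg$flat_dim, cfg$fc_hidden),
                 fc2 = linear_init(cfg$fc_hidden, 2L,
                                   sd = sqrt(1 / cfg$fc_hidden)))
  structure(list(cfg = cfg, params = params, threshold = 0.5),
            class = "slp_state")
}

slp_forward_cache <- function(patches, state, keep_cache = FALSE) {
  cfg <- state$cfg
  d <- dim(patches)
  if (d[1L] != cfg$patch_side || d[2L] != cfg$patch_side) {
    stop("patches must be ", cfg$patch_side, " x ", cfg$patch_side, " x 3")
  }
  X <- patches / 255
  caches <- list()
  for (b in seq_along(state$params$conv)) {
    cv <- conv_forward(X, state$params$conv[[b]])
    A <- relu(cv$out)
    mp <- maxpool_forward(A)
    X <- mp$out
    caches[[b]] <- list(conv = cv$cache, pre = cv$out, pool = mp$cache)
  }
  fin <- maxpool_forward(X)
  X <- fin$out
  n <- d[4L]
  flat <- t(matrix(X, cfg$flat_dim, n))
  h1pre <- linear_forward(flat, state$params$fc1)
  h1 <- relu(h1pre)
  logits <- linear_forward(h1, state$params$fc2)
  mx <- pmax(logits[, 1L], logits[, 2L])
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)                       # columns: non-tumor, tumor
  res <- list(probs = probs)
  if (keep_cache) {
    res$cache <- list(blocks = caches, fin = fin$cache, flat = flat,
                      h1pre = h1pre, h1 = h1, logits = logits)
  }
  res
}

#' Tumor probability of each spot patch
#'
#' Runs the classifier and returns the softmax probability of the tumor
#' class, one value in `[0, 1]` per patch.
#'
#' @param patches `side x side x 3 x g` patch stack (0--255; resized to the
#'   configured side internally).
#' @param state An `slp_state`.
#' @return Numeric vector of length `g` (named by spot id when available).
#' @export
slp_forward <- function(patches, state) {
  patches <- resize_stack(patches, state$cfg$patch_side)
  pr <- slp_forward_cache(patches, state)$probs[, 2L]
  ids <- dimnames(patches)[[4L]]
  if (!is.null(ids)) names(pr) <- ids
  pr
}

slp_backward <- function(fw, y, state) {
  # y: 0/1 tumor indicator; cross-entropy with softmax output
  p <- state$params
  ch <- fw$cache
  n <- length(y)
  grads <- tree_map(function(x) x * 0, p)
  targets <- cbind(1 - y, y)
  dlogits <- (fw$probs - targets) / n
  lb <- linear_backward(dlogits, ch$h1, p$fc2)
  grads$fc2$W <- lb$dW; grads$fc2$b <- lb$db
  dh1 <- relu_grad(lb$dX, ch$h1pre)
  lb <- linear_backward(dh1, ch$flat, p$fc1)
  grads$fc1$W <- lb$dW; grads$fc1$b <- lb$db
  cfg <- state$cfg
  dX <- array(t(lb$dX), c(cfg$final_side, cfg$final_side,
                          cfg$conv_channels[length(cfg$conv_channels)], n))
  dX <- maxpool_backward(dX, ch$fin)
  for (b in rev(seq_along(p$conv))) {
    blk <- ch$blocks[[b]]
    dX <- maxpool_backward(dX, blk$pool)
    dX <- relu_grad(dX, blk$pre)
    cb <- conv_backward(dX, blk$conv)
    grads$conv[[b]]$W <- cb$dW
    grads$conv[[b]]$b <- cb$db
    dX <- cb$dX
  }
  grads
}

#' Youden-index threshold selection
#'
#' Scans the finite set of observed probabilities as candidate thresholds
#' (classification rule: tumor iff probability >= threshold) and returns
#' the candidate maximizing Youden's J = sensitivity + specificity - 1.
#' Ties are broken toward the smallest threshold.
#'
#' @param probs Numeric vector of tumor probabilities.
#' @param labels Binary vector (1 = tumor); both classes must be present.
#' @return The selected threshold.
#' @export
youden_threshold <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("youden_threshold needs both classes present")
  }
  cand <- sort(unique(probs))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  # integer scoring (TP * nneg + TN * npos is a monotone transform of J)
  # keeps ties exact, so which.max deterministically picks the smallest
  # tied threshold
  J <- vapply(cand, function(t) {
    tp <- sum(probs >= t & labels == 1L)
    tn <- sum(probs < t & labels == 0L)
    tp * nneg + tn * npos
  }, numeric(1))
  cand[which.max(J)]
}

#' Threshold probabilities into tumor calls
#'
#' @param probs Numeric vector of tumor probabilities.
#' @param threshold Decision threshold; a spot is tumor iff
#'   `prob >= threshold`.
#' @return Integer 0/1 vector (1 = tumor).
#' @export
classify_spots <- function(probs, threshold) {
  as.integer(probs >= threshold)
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR / (P + R)`; defined as 0 when
#' precision + recall is 0 (no true or predicted positives overlap).
#'
#' @param pred,truth Binary 0/1 vectors.
#' @return Fraction in `[0, 1]`.
#' @export
f1_score <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- as.integer(pred); truth <- as.integer(truth)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  if (tp == 0L) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Train the spot label predictor
#'
#' The classifier is optimized by cross-entropy (mini-batches, Adam); the
#' stated goal of maximizing F1 is realized by model selection: after each
#' epoch the decision threshold is chosen on a stratified held-out
#' validation split by Youden's index, and the epoch whose validation F1 at
#' that threshold is highest supplies the returned parameters and
#' threshold. Seeded and reproducible.
#'
#' @param samples List of samples, each a list with `patches`
#'   (`side x side x 3 x g`) and `labels` (character `"tumor"`/`"non_tumor"`
#'   or binary 0/1 vector of length `g`).
#' @param cfg An [slp_config()].
#' @param batch_size Mini-batch size (default 64).
#' @param verbose Print validation F1 per epoch.
#' @return Trained `slp_state` with `$threshold` and `$val_f1`.
#' @export
train_slp <- function(samples, cfg, batch_size = 64L, verbose = FALSE) {
  stopifnot(length(samples) >= 1L)
  to01 <- function(l) {
    if (is.character(l) || is.factor(l)) as.integer(as.character(l) == "tumor")
    else as.integer(l)
  }
  side <- cfg$patch_side
  stacks <- lapply(samples, function(s) resize_stack(s$patches, side))
  labels <- unlist(lapply(samples, function(s) to01(s$labels)))
  n <- length(labels)
  X <- array(0, c(side, side, 3L, n))
  at <- 0L
  for (s in stacks) {
    k <- dim(s)[4L]
    X[, , , (at + 1L):(at + k)] <- s
    at <- at + k
  }
  if (length(unique(labels)) < 2L) stop("training labels contain one class")

  set.seed(cfg$seed)
  state <- slp_init(cfg)
  # stratified validation split
  idx_pos <- which(labels == 1L); idx_neg <- which(labels == 0L)
  val <- c(sample(idx_pos, max(1L, round(cfg$val_fraction * length(idx_pos)))),
           sample(idx_neg, max(1L, round(cfg$val_fraction * length(idx_neg)))))
  tr <- setdiff(seq_len(n), val)
  opt <- adam_init(state$params)
  best <- list(f1 = -1, params = state$params, threshold = 0.5)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    for (start in seq(1L, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, length(ord))]
      fw <- slp_forward_cache(X[, , , bi, drop = FALSE], state,
                              keep_cache = TRUE)
      grads <- slp_backward(fw, labels[bi], state)
      upd <- adam_step(state$params, grads, opt, lr = cfg$learning_rate)
      state$params <- upd$params
      opt <- upd$opt
    }
    vp <- slp_forward_cache(X[, , , val, drop = FALSE], state)$probs[, 2L]
    thr <- tryCatch(youden_threshold(vp, labels[val]), error = function(e) 0.5)
    f1 <- f1_score(classify_spots(vp, thr), labels[val])
    if (f1 > best$f1) best <- list(f1 = f1, params = state$params,
                                   threshold = thr)
    if (verbose) message(sprintf("epoch %d: val F1 %.3f (thr %.3f)",
                                 epoch, f1, thr))
  }
  state$params <- best$params
  state$threshold <- best$threshold
  state$val_f1 <- best$f1
  state
}

#' Average expression over tumor spots
#'
#' Column mean of an expression matrix restricted to tumor-masked rows --
#' the denoised sample-level profile used for downstream analyses.
#'
#' @param expr `g x p` expression matrix.
#' @param tumor_mask Binary 0/1 (or logical) vector of length `g`.
#' @return Named length-`p` vector.
#' @export
tumor_average_expression <- function(expr, tumor_mask) {
  stopifnot(nrow(expr) == length(tumor_mask))
  mask <- as.logical(as.integer(tumor_mask))
  if (!any(mask)) {
    stop("no tumor spots in mask; rerun with an all-spot average ",
         "(tumor_mask = rep(1, nrow(expr))) if a fallback is intended")
  }
  colMeans(expr[mask, , drop = FALSE])
}
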