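# Automatic cropping: a small from-scratch 2D CNN decides, per axis, whether
# a slice contains the object; the first/last positive slices plus a safety
# buffer give the bounding box. Trained with the two-phase schedule of the
# transfer-learning recipe: first the classification head only (Adam,
# lr 1e-3), then the whole network. Because the backbone here is a small
# from-scratch CNN rather than a pretrained one, the full-network phase
# defaults to the same 1e-3 rate (a 1e-5 fine-tune rate, appropriate for a
# pretrained backbone, would leave random convolutions untrained).

#' Crop classifier configuration
#'
#' @param epochs_head,epochs_ft epochs of head-only training and full
#'   fine-tuning (the two training phases).
#' @param lr_head,lr_ft Adam learning rates of the two phases.
#' @param channels feature channels of the two conv blocks.
#' @param batch_size slices per minibatch.
#' @param dropout dropout probability before the final dense layer.
#' @param threshold slice-present decision threshold in (0, 1).
#' @param buffer_slices safety buffer at the 256-slice reference scale; the
#'   effective buffer is `max(2, round(buffer_slices * axis_len / 256))`.
#' @param holdout fraction of slices held out for the validation accuracy log.
#' @param seed RNG seed.
#' @return object of class `crop_config`.
#' @export
crop_config <- function(epochs_head = 50, epochs_ft = 50, lr_head = 1e-3,
                        lr_ft = 1e-3, channels = c(4, 8), batch_size = 16,
                        dropout = 0.3, threshold = 0.5, buffer_slices = 25,
                        holdout = 0.25, seed = 1L) {
  if (threshold <= 0 || threshold >= 1)
    stop("crop_config: threshold must be in (0, 1)")
  if (buffer_slices < 0) stop("crop_config: buffer_slices must be >= 0")
  structure(list(epochs_head = epochs_head, epochs_ft = epochs_ft,
                 lr_head = lr_head, lr_ft = lr_ft, channels = channels,
                 batch_size = batch_size, dropout = dropout,
                 threshold = threshold, buffer_slices = buffer_slices,
                 holdout = holdout, seed = as.integer(seed)),
            class = "crop_config")
}

buffer_for <- function(axis_len, buffer_slices = 25)
  max(2L, as.integer(round(buffer_slices * axis_len / 256)))

# standardize one slice matrix, pad to multiples of 4, return (1,h,w) array
prep_slice <- function(s) {
  v <- stats::var(as.vector(s))
  s <- if (v > 0) (s - mean(s)) / sqrt(v) else s * 0
  h <- ceiling(nrow(s) / 4) * 4; w <- ceiling(ncol(s) / 4) * 4
  out <- matrix(0, h, w)
  out[seq_len(nrow(s)), seq_len(ncol(s))] <- s
  array(out, c(1L, h, w))
}

slices_along <- function(arr, axis) {
  n <- dim(arr)[axis]
  lapply(seq_len(n), function(s) switch(axis,
    arr[s, , , drop = TRUE], arr[, s, , drop = TRUE], arr[, , s, drop = TRUE]))
}

clf_init <- function(cfg) {
  ch <- cfg$channels
  params <- list(); state <- list()
  params$c1_W <- he_init(27 * 1, ch[1], 27)
  params$c1_g <- rep(1, ch[1]); params$c1_b <- rep(0, ch[1])
  state$c1_rm <- rep(0, ch[1]); state$c1_rv <- rep(1, ch[1])
  params$c2_W <- he_init(27 * ch[1], ch[2], 27 * ch[1])
  params$c2_g <- rep(1, ch[2]); params$c2_b <- rep(0, ch[2])
  state$c2_rm <- rep(0, ch[2]); state$c2_rv <- rep(1, ch[2])
  params$head_W <- he_init(ch[2], 1, ch[2])
  params$head_b <- 0
  list(params = params, state = state)
}

clf_fwd <- function(net, X, shape, B, training, cfg) {
  params <- net$params; state <- net$state
  cache <- list()
  r <- conv_bn_relu_fwd("c1", X, shape, B, params, state, training, cache)
  state <- r$state; cache <- r$cache
  child1 <- pool_table(shape, c(1L, 2L, 2L), B)
  p1 <- pool_fwd(r$A, child1)
  if (training) cache$pool1 <- list(arg = p1$arg, n_in = nrow(r$A))
  s2 <- shape %/% c(1L, 2L, 2L)
  r2 <- conv_bn_relu_fwd("c2", p1$Y, s2, B, params, state, training, cache)
  state <- r2$state; cache <- r2$cache
  child2 <- pool_table(s2, c(1L, 2L, 2L), B)
  p2 <- pool_fwd(r2$A, child2)
  if (training) cache$pool2 <- list(arg = p2$arg, n_in = nrow(r2$A))
  s3 <- s2 %/% c(1L, 2L, 2L)
  N3 <- prod(s3)
  grp <- rep(seq_len(B), each = N3)
  G <- rowsum(p2$Y, grp) / N3
  if (training && cfg$dropout > 0) {
    keep <- matrix(runif(length(G)) >= cfg$dropout, nrow(G), ncol(G))
    cache$drop <- keep
    G <- G * keep / (1 - cfg$dropout)
  }
  cache$head_X <- G
  z <- as.vector(G %*% params$head_W) + params$head_b
  prob <- 1 / (1 + exp(-z))
  list(prob = prob, z = z, cache = cache, state = state,
       shapes = list(shape, s2, s3), N3 = N3)
}

clf_bwd <- function(net, fw, y, B, cfg, w = rep(1, B)) {
  params <- net$params; cache <- fw$cache
  grads <- list()
  dz <- w * (fw$prob - y) / B                  # weighted BCE with sigmoid
  G <- cache$head_X
  grads$head_W <- crossprod(G, dz)
  grads$head_b <- sum(dz)
  dG <- matrix(dz, B, 1) %*% t(params$head_W)
  if (!is.null(cache$drop)) dG <- dG * cache$drop / (1 - cfg$dropout)
  N3 <- fw$N3
  dP2 <- dG[rep(seq_len(B), each = N3), , drop = FALSE] / N3
  s2 <- fw$shapes[[2]]; s3 <- fw$shapes[[3]]
  child2 <- pool_table(s2, c(1L, 2L, 2L), B)
  dA2 <- pool_bwd(dP2, cache$pool2, child2, cache$pool2$n_in)
  r <- conv_bn_relu_bwd("c2", dA2, s2, B, params, cache, grads)
  grads <- r$grads
  child1 <- pool_table(fw$shapes[[1]], c(1L, 2L, 2L), B)
  dA1 <- pool_bwd(r$dX, cache$pool1, child1, cache$pool1$n_in)
  r <- conv_bn_relu_bwd("c1", dA1, fw$shapes[[1]], B, params, cache, grads,
                        need_dX = FALSE)
  r$grads
}

clf_train_phase <- function(net, Xs, y, cfg, lr, epochs, mask) {
  if (length(Xs) == 0) return(net)
  state <- list(m = zeros_like(net$params), v = zeros_like(net$params))
  iter <- 0
  shape <- dim(Xs[[1]])
  N <- prod(shape)
  # class-balanced loss weights: present/absent slices are often very
  # unbalanced (an uncropped scan has few object-free slices on some axes)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  wts <- ifelse(y == 1, length(y) / (2 * n1), length(y) / (2 * n0))
  for (e in seq_len(epochs)) {
    ord <- sample(length(Xs))
    for (s0 in seq(1, length(ord), by = cfg$batch_size)) {
      sel <- ord[s0:min(s0 + cfg$batch_size - 1, length(ord))]
      B <- length(sel)
      X <- matrix(0, B * N, 1)
      for (j in seq_len(B))
        X[((j - 1) * N + 1):(j * N), 1] <- as.vector(Xs[[sel[j]]])
      fw <- clf_fwd(net, X, shape, B, training = TRUE, cfg)
      net$state <- fw$state
      grads <- clf_bwd(net, fw, y[sel], B, cfg, w = wts[sel])
      iter <- iter + 1
      st <- adam_step(net$params, grads, state, lr, iter = iter, mask = mask)
      net$params <- st$params; state <- st$state
    }
  }
  net
}

clf_predict <- function(net, Xs, cfg) {
  if (length(Xs) == 0) return(numeric(0))
  shape <- dim(Xs[[1]])
  N <- prod(shape)
  probs <- numeric(length(Xs))
  for (s0 in seq(1, length(Xs), by = cfg$batch_size)) {
    sel <- s0:min(s0 + cfg$batch_size - 1, length(Xs))
    B <- length(sel)
    X <- matrix(0, B * N, 1)
    for (j in seq_len(B))
      X[((j - 1) * N + 1):(j * N), 1] <- as.vector(Xs[[sel[j]]])
    fw <- clf_fwd(net, X, shape, B, training = FALSE, cfg)
    probs[sel] <- fw$prob
  }
  probs
}

#' Train the per-axis slice classifiers for automatic cropping
#'
#' For each of the three axes, slices of the training volumes are labelled
#' "object present" when they contain any non-background label voxel, and a
#' small 2D CNN (two conv+BN+ReLU+pool blocks, global average pooling,
#' dropout, sigmoid head) is trained in two phases: head only at
#' `lr_head`, then the full network at `lr_ft`.
#'
#' @param pairs list of pairs, each a list with `image` ([volume3d()]) and
#'   `labels` ([label_volume()]).
#' @param cfg a [crop_config()].
#' @return a `crop_model` with per-axis networks, decision threshold,
#'   buffer setting and a held-out slice accuracy log.
#' @export
train_crop_classifier <- function(pairs, cfg = crop_config()) {
  if (length(pairs) < 2)
    stop("train_crop_classifier: need at least 2 training volumes")
  if (cfg$epochs_head + cfg$epochs_ft < 1)
    stop("train_crop_classifier: zero training epochs requested")
  axes <- 1:3
  with_seed(cfg$seed, {
    nets <- lapply(axes, function(ax) {
      Xs <- list(); y <- numeric(0)
      for (p in pairs) {
        img <- as_vol_array(p$image)
        lab <- as_vol_array(p$labels)
        sl <- slices_along(img, ax)
        ll <- slices_along(lab, ax)
        Xs <- c(Xs, lapply(sl, prep_slice))
        y <- c(y, vapply(ll, function(s) as.numeric(any(s != 0)), numeric(1)))
      }
      if (length(unique(y)) < 2)
        stop("train_crop_classifier: all slices are one class on axis ", ax)
      hold <- seq_along(Xs) %% round(1 / cfg$holdout) == 0
      net <- clf_init(cfg)
      head_mask <- lapply(names(net$params), function(nm) grepl("^head", nm))
      names(head_mask) <- names(net$params)
      net <- clf_train_phase(net, Xs[!hold], y[!hold], cfg, cfg$lr_head,
                             cfg$epochs_head, head_mask)
      net <- clf_train_phase(net, Xs[!hold], y[!hold], cfg, cfg$lr_ft,
                             cfg$epochs_ft, mask = NULL)
      acc <- if (any(hold)) {
        ph <- clf_predict(net, Xs[hold], cfg)
        mean((ph >= cfg$threshold) == (y[hold] == 1))
      } else NA_real_
      net$val_accuracy <- acc
      net
    })
    structure(list(nets = nets, cfg = cfg,
                   val_accuracy = vapply(nets, `[[`, numeric(1),
                                         "val_accuracy")),
              class = "crop_model")
  })
}

#' Predict a bounding box with the crop classifiers
#'
#' Applies the three per-axis slice classifiers; on each axis the box spans
#' the first to the last slice with predicted presence probability at or
#' above the threshold, expanded by the scaled safety buffer and clamped to
#' the volume.
#'
#' @param v a [volume3d()] or 3D array.
#' @param m a `crop_model` from [train_crop_classifier()].
#' @return 2x3 matrix bbox (rows lo/hi, columns z, y, x).
#' @export
auto_crop <- function(v, m) {
  stopifnot(inherits(m, "crop_model"))
  arr <- as_vol_array(v)
  cfg <- m$cfg
  bbox <- matrix(0L, 2, 3, dimnames = list(c("lo", "hi"), c("z", "y", "x")))
  for (ax in 1:3) {
    Xs <- lapply(slices_along(arr, ax), prep_slice)
    probs <- clf_predict(m$nets[[ax]], Xs, cfg)
    present <- which(probs >= cfg$threshold)
    if (!length(present))
      stop("auto_crop: no slice predicted to contain the object on axis ", ax)
    buf <- buffer_for(dim(arr)[ax], cfg$buffer_slices)
    bbox[1, ax] <- max(1L, min(present) - buf)
    bbox[2, ax] <- min(dim(arr)[ax], max(present) + buf)
  }
  bbox
}
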