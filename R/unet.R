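#' Network configuration
#'
#' Hyperparameters of the patch-based 3D U-Net. The default profile is the
#' GPU-scale configuration used for full micro-CT scans (patch 64, stride 32,
#' volumes rescaled to 256^3, channels doubling 32 to 1024, SGD with
#' learning rate 0.01, decay 1e-6, momentum 0.9 with Nesterov enabled, 200
#' epochs, batch 24). [net_profile()] provides smaller CPU-friendly variants.
#'
#' @param patch_size cubic patch edge; must be divisible by 2^(levels-1).
#' @param stride patch grid stride; at most `patch_size`.
#' @param scaled_shape working shape volumes are resampled to before
#'   patch extraction.
#' @param base_channels,max_channels feature channels at the first level and
#'   at the bottleneck; channels double per level.
#' @param epochs,batch_size training schedule.
#' @param learning_rate,decay,momentum,nesterov SGD settings.
#' @param n_labels number of output classes including background.
#' @param val_freq validation cadence in epochs (stitched full-volume Dice).
#' @param select_best keep the weights of the best validation epoch rather
#'   than the last epoch.
#' @param fusion `"average"` (mean class scores over overlapping patches,
#'   the default) or `"vote"` (per-patch argmax majority).
#' @param seed RNG seed for weight init and patch shuffling.
#' @return object of class `net_config`.
#' @export
net_config <- function(patch_size = 64, stride = 32,
                       scaled_shape = c(256, 256, 256),
                       base_channels = 32, max_channels = 1024,
                       epochs = 200, batch_size = 24,
                       learning_rate = 0.01, decay = 1e-6,
                       momentum = 0.9, nesterov = TRUE,
                       n_labels = 7, val_freq = 1, select_best = TRUE,
                       fusion = c("average", "vote"), seed = 1L) {
  fusion <- match.arg(fusion)
  levels <- log2(max_channels / base_channels) + 1
  if (levels != round(levels) || levels < 2)
    stop("net_config: max_channels must be base_channels * 2^k, k >= 1")
  levels <- as.integer(round(levels))
  if (patch_size %% 2^(levels - 1) != 0)
    stop("net_config: patch_size must be divisible by 2^(levels-1) = ",
         2^(levels - 1))
  if (stride > patch_size) stop("net_config: stride must be <= patch_size")
  if (stride < 1 || patch_size < 2) stop("net_config: invalid patch/stride")
  structure(
    list(patch_size = as.integer(patch_size), stride = as.integer(stride),
         scaled_shape = as.integer(scaled_shape),
         base_channels = as.integer(base_channels),
         max_channels = as.integer(max_channels), levels = levels,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, decay = decay, momentum = momentum,
         nesterov = nesterov, n_labels = as.integer(n_labels),
         val_freq = as.integer(val_freq), select_best = isTRUE(select_best),
         fusion = fusion, seed = as.integer(seed)),
    class = "net_config"
  )
}

#' Named network profiles
#'
#' `"paper"`: the full GPU-scale configuration (see [net_config()] defaults).
#' `"desk"`: a reduced single-CPU profile (96^3 working shape, patch 64,
#' base 8 / max 128 channels, 40 epochs, batch 4).
#' `"micro"`: a small profile for tests and demonstrations (32^3 working
#' shape, patch 16, stride 8, base 4 / max 32 channels, batch 4).
#'
#' @param name profile name.
#' @param ... overrides passed to [net_config()].
#' @return a `net_config`.
#' @export
net_profile <- function(name = c("desk", "paper", "micro"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    paper = list(),
    desk = list(patch_size = 64, stride = 32, scaled_shape = c(96, 96, 96),
                base_channels = 8, max_channels = 128, epochs = 40,
                batch_size = 4),
    micro = list(patch_size = 16, stride = 8, scaled_shape = c(32, 32, 32),
                 base_channels = 4, max_channels = 32, epochs = 15,
                 batch_size = 4)
  )
  do.call(net_config, utils::modifyList(args, list(...)))
}

#' Build an untrained 3D U-Net
#'
#' Encoder: per level, two 3x3x3 convolutions each followed by batch
#' normalisation and ReLU, then 2x2x2 max pooling (stride 2); channels
#' double per level from `base_channels` to `max_channels`. Decoder: nearest
#' upsampling, concatenation with the corresponding encoder feature map,
#' then two conv+BN+ReLU blocks. A final 1x1x1 convolution maps to
#' `n_labels` classes. Weights are He-normal initialized under `cfg$seed`.
#'
#' @param cfg a [net_config()].
#' @return an untrained `unet_model` (weights, running statistics, config).
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  L <- cfg$levels
  ch <- cfg$base_channels * 2^(0:(L - 1))
  params <- list(); state <- list()
  add_conv_bn <- function(nm, cin, cout) {
    params[[paste0(nm, "_W")]] <<- he_init(27 * cin, cout, 27 * cin)
    params[[paste0(nm, "_g")]] <<- rep(1, cout)
    params[[paste0(nm, "_b")]] <<- rep(0, cout)
    state[[paste0(nm, "_rm")]] <<- rep(0, cout)
    state[[paste0(nm, "_rv")]] <<- rep(1, cout)
  }
  with_seed(cfg$seed, {
    for (l in seq_len(L)) {
      add_conv_bn(paste0("enc", l, "a"), if (l == 1) 1 else ch[l - 1], ch[l])
      add_conv_bn(paste0("enc", l, "b"), ch[l], ch[l])
    }
    for (l in rev(seq_len(L - 1))) {
      add_conv_bn(paste0("dec", l, "a"), ch[l] + ch[l + 1], ch[l])
      add_conv_bn(paste0("dec", l, "b"), ch[l], ch[l])
    }
    params$out_W <- he_init(ch[1], cfg$n_labels, ch[1])
    params$out_b <- rep(0, cfg$n_labels)
  })
  structure(
    list(params = params, state = state, cfg = cfg, trained = FALSE,
         history = NULL, best_epoch = NA_integer_),
    class = "unet_model"
  )
}

#' Number of trainable parameters
#' @param m a `unet_model`.
#' @param encoder_only count only encoder parameters.
#' @return integer count.
#' @export
n_parameters <- function(m, encoder_only = FALSE) {
  nms <- names(m$params)
  if (encoder_only) nms <- grep("^enc", nms, value = TRUE)
  sum(vapply(m$params[nms], length, integer(1)))
}

conv_bn_relu_fwd <- function(nm, X, shape, batch, params, state, training,
                             cache) {
  W <- params[[paste0(nm, "_W")]]
  cf <- conv_fwd(X, W, shape, batch)
  bn <- bn_fwd(cf$Y, params[[paste0(nm, "_g")]], params[[paste0(nm, "_b")]],
               state[[paste0(nm, "_rm")]], state[[paste0(nm, "_rv")]],
               training)
  A <- bn$Y
  mask <- A > 0
  A[!mask] <- 0
  if (training) {
    cache[[nm]] <- list(col = cf$col, Ybn = bn, relu = mask)
    state[[paste0(nm, "_rm")]] <- bn$run_mean
    state[[paste0(nm, "_rv")]] <- bn$run_var
  }
  list(A = A, state = state, cache = cache)
}

conv_bn_relu_bwd <- function(nm, dA, shape, batch, params, cache, grads,
                             need_dX = TRUE) {
  cc <- cache[[nm]]
  dA[!cc$relu] <- 0
  bb <- bn_bwd(dA, cc$Ybn, params[[paste0(nm, "_g")]])
  grads[[paste0(nm, "_g")]] <- bb$dgamma
  grads[[paste0(nm, "_b")]] <- bb$dbeta
  cb <- conv_bwd(cc$col, bb$dX, params[[paste0(nm, "_W")]], shape, batch,
                 need_dX)
  grads[[paste0(nm, "_W")]] <- cb$dW
  list(dX = cb$dX, grads = grads)
}

# Forward pass over a minibatch of patches. X: (batch*N x 1) matrix.
unet_fwd <- function(model, X, shape, batch, training = FALSE) {
  cfg <- model$cfg
  L <- cfg$levels
  params <- model$params; state <- model$state
  cache <- list(); skips <- list(); shapes <- list()
  s <- shape
  A <- X
  for (l in seq_len(L)) {
    shapes[[l]] <- s
    r <- conv_bn_relu_fwd(paste0("enc", l, "a"), A, s, batch, params, state,
                          training, cache)
    state <- r$state; cache <- r$cache
    r <- conv_bn_relu_fwd(paste0("enc", l, "b"), r$A, s, batch, params, state,
                          training, cache)
    state <- r$state; cache <- r$cache
    A <- r$A
    if (l < L) {
      skips[[l]] <- A
      child <- pool_table(s, c(2L, 2L, 2L), batch)
      pf <- pool_fwd(A, child)
      if (training) cache[[paste0("pool", l)]] <-
          list(arg = pf$arg, n_in = nrow(A))
      A <- pf$Y
      s <- s %/% 2L
    }
  }
  for (l in rev(seq_len(L - 1))) {
    parent <- upsample_table(s, c(2L, 2L, 2L), batch)
    U <- upsample_fwd(A, parent)
    s <- s * 2L
    if (training) cache[[paste0("up", l)]] <- list(n_coarse = prod(s %/% 2L) * batch)
    A <- cbind(U, skips[[l]])
    r <- conv_bn_relu_fwd(paste0("dec", l, "a"), A, s, batch, params, state,
                          training, cache)
    state <- r$state; cache <- r$cache
    r <- conv_bn_relu_fwd(paste0("dec", l, "b"), r$A, s, batch, params, state,
                          training, cache)
    state <- r$state; cache <- r$cache
    A <- r$A
  }
  logits <- sweep(A %*% params$out_W, 2, params$out_b, `+`)
  if (training) cache$out_X <- A
  list(logits = logits, cache = cache, state = state, shapes = shapes)
}

unet_bwd <- function(model, dlogits, fwd, shape, batch) {
  cfg <- model$cfg
  L <- cfg$levels
  params <- model$params; cache <- fwd$cache
  grads <- list()
  grads$out_W <- crossprod(cache$out_X, dlogits)
  grads$out_b <- colSums(dlogits)
  dA <- dlogits %*% t(params$out_W)
  dskips <- list()
  s <- shape
  for (l in seq_len(L - 1)) {
    r <- conv_bn_relu_bwd(paste0("dec", l, "b"), dA, s, batch, params, cache,
                          grads)
    grads <- r$grads
    r <- conv_bn_relu_bwd(paste0("dec", l, "a"), r$dX, s, batch, params, cache,
                          grads)
    grads <- r$grads
    # split concat gradient: first columns belong to the upsampled path
    cup <- ncol(r$dX) - ncol(cache[[paste0("enc", l, "b")]]$relu)
    dU <- r$dX[, seq_len(cup), drop = FALSE]
    dskips[[l]] <- r$dX[, (cup + 1):ncol(r$dX), drop = FALSE]
    parent <- upsample_table(s %/% 2L, c(2L, 2L, 2L), batch)
    dA <- upsample_bwd(dU, parent, cache[[paste0("up", l)]]$n_coarse)
    s <- s %/% 2L
  }
  # encoder, from the bottleneck up
  for (l in rev(seq_len(L))) {
    r <- conv_bn_relu_bwd(paste0("enc", l, "b"), dA, s, batch, params, cache,
                          grads)
    grads <- r$grads
    r <- conv_bn_relu_bwd(paste0("enc", l, "a"), r$dX, s, batch, params, cache,
                          grads, need_dX = l > 1)
    grads <- r$grads
    if (l > 1) {
      child <- pool_table(s * 2L, c(2L, 2L, 2L), batch)
      pc <- cache[[paste0("pool", l - 1)]]
      dA <- pool_bwd(r$dX, pc, child, pc$n_in)
      dA <- dA + dskips[[l - 1]]
      s <- s * 2L
    }
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decompose a volume into an overlapping patch grid
#'
#' The volume is zero-padded up to the next stride multiple so that a
#' regular grid of cubic patches covers it completely; the source offsets
#' are recorded so that stitching is exact and the padding can be removed
#' after inference.
#'
#' @param v a [volume3d()] or 3D array.
#' @param patch cubic patch edge.
#' @param stride grid stride (<= patch).
#' @return list with `offsets` (n x 3 matrix of 1-based patch starts in the
#'   padded volume), `padded_dim`, `pad` (voxels added per axis), `patch`,
#'   `stride`, and `padded` (the padded array).
#' @export
extract_patches <- function(v, patch, stride) {
  arr <- as_vol_array(v)
  d <- dim(arr)
  if (stride > patch) stop("extract_patches: stride must be <= patch")
  n_steps <- pmax(0, ceiling((d - patch) / stride))
  target <- patch + n_steps * stride
  if (any(target < patch))
    stop("extract_patches: patch larger than padded volume")
  pad <- target - d
  if (any(pad > 0)) {
    padded <- array(0, target)
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  } else padded <- arr
  pos <- lapply(1:3, function(a) seq(1L, target[a] - patch + 1L, by = stride))
  offsets <- as.matrix(expand.grid(z = pos[[1]], y = pos[[2]], x = pos[[3]]))
  list(offsets = offsets, padded_dim = target, pad = pad,
       patch = as.integer(patch), stride = as.integer(stride), padded = padded)
}

get_patch <- function(padded, off, patch) {
  padded[off[1]:(off[1] + patch - 1), off[2]:(off[2] + patch - 1),
         off[3]:(off[3] + patch - 1)]
}

# Forward a set of patches through the model and fuse class scores into a
# full (padded) volume; returns the argmax label array (values 0..K-1).
predict_padded <- function(model, ep) {
  cfg <- model$cfg
  K <- cfg$n_labels
  patch <- ep$patch
  N <- patch^3
  n_pat <- nrow(ep$offsets)
  scores <- matrix(0, prod(ep$padded_dim), K)
  vox_of <- function(off) {
    zi <- off[1]:(off[1] + patch - 1); yi <- off[2]:(off[2] + patch - 1)
    xi <- off[3]:(off[3] + patch - 1)
    d <- ep$padded_dim
    as.vector(outer(outer(zi, (yi - 1) * d[1], `+`),
                    (xi - 1) * d[1] * d[2], `+`))
  }
  bs <- cfg$batch_size
  b_start <- seq(1L, n_pat, by = bs)
  for (s0 in b_start) {
    idx <- s0:min(s0 + bs - 1L, n_pat)
    B <- length(idx)
    X <- matrix(0, B * N, 1)
    for (j in seq_along(idx))
      X[((j - 1) * N + 1):(j * N), 1] <-
        as.vector(get_patch(ep$padded, ep$offsets[idx[j], ], patch))
    fw <- unet_fwd(model, X, rep(patch, 3L), B, training = FALSE)
    P <- softmax_rows(fw$logits)
    if (cfg$fusion == "vote") {
      cls <- max.col(P, ties.method = "first")
      P <- matrix(0, nrow(P), K)
      P[cbind(seq_len(nrow(P)), cls)] <- 1
    }
    for (j in seq_along(idx)) {
      vv <- vox_of(ep$offsets[idx[j], ])
      scores[vv, ] <- scores[vv, ] + P[((j - 1) * N + 1):(j * N), , drop = FALSE]
    }
  }
  lab <- max.col(scores, ties.method = "first") - 1L
  array(as.integer(lab), ep$padded_dim)
}

unpad <- function(arr, orig_dim) {
  arr[seq_len(orig_dim[1]), seq_len(orig_dim[2]), seq_len(orig_dim[3]),
      drop = FALSE]
}

# scale + standardize an image/label pair to the network working shape
prep_pair <- function(img, lab, cfg) {
  ia <- as_vol_array(img)
  la <- if (is.null(lab)) NULL else as_vol_array(lab)
  if (!identical(dim(ia), cfg$scaled_shape))
    ia <- resize_array(ia, cfg$scaled_shape, "trilinear")
  ia <- normalize_intensity(ia)
  if (!is.null(la) && !identical(dim(la), cfg$scaled_shape))
    la <- resize_array(la, cfg$scaled_shape, "nearest")
  list(img = ia, lab = la)
}

#' Train the 3D U-Net on image/label pairs
#'
#' Volumes are rescaled to the working shape (trilinear for images, nearest
#' for labels), standardized, and decomposed into overlapping patches.
#' Training minimizes voxel-wise categorical cross-entropy with SGD
#' (Nesterov momentum, inverse-time decay). After each epoch (or every
#' `val_freq` epochs) the current network segments the validation volumes
#' by full stitched inference and the mean total Dice against the validation
#' labels is recorded; the weights of the best validation epoch are kept.
#'
#' @param train,val lists of pairs; each pair is a list with elements
#'   `image` ([volume3d()]) and `labels` ([label_volume()]).
#' @param cfg a [net_config()].
#' @param verbose print per-epoch progress.
#' @return a trained `unet_model` with `history` (per-epoch loss, accuracy,
#'   validation Dice) and `best_epoch`.
#' @export
train_unet <- function(train, val = list(), cfg = net_profile("desk"),
                       verbose = FALSE) {
  if (length(train) < 1) stop("train_unet: need at least one training pair")
  if (cfg$epochs < 1) stop("train_unet: epochs must be >= 1")
  if (cfg$select_best && length(val) == 0)
    stop("train_unet: best-epoch selection requires validation pairs ",
         "(set select_best = FALSE to keep the final epoch)")
  K <- cfg$n_labels
  for (p in train) {
    ids <- unique(as.vector(as_vol_array(p$labels)))
    if (any(ids < 0 | ids >= K))
      stop("train_unet: label id outside 0..", K - 1)
  }
  prep <- lapply(train, function(p) prep_pair(p$image, p$labels, cfg))
  vprep <- lapply(val, function(p) prep_pair(p$image, p$labels, cfg))

  patch <- cfg$patch_size
  N <- patch^3
  eps <- lapply(prep, function(p) extract_patches(p$img, patch, cfg$stride))
  lab_eps <- lapply(prep, function(p) extract_patches(p$lab, patch, cfg$stride))
  refs <- do.call(rbind, lapply(seq_along(eps), function(vi)
    cbind(vol = vi, idx = seq_len(nrow(eps[[vi]]$offsets)))))

  model <- build_unet(cfg)
  vel <- zeros_like(model$params)
  iter <- 0
  best <- list(dice = -Inf, epoch = NA_integer_, params = NULL, state = NULL)
  hist <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric(),
                     val_dice = numeric())

  with_seed(cfg$seed + 1L, {
    for (ep_i in seq_len(cfg$epochs)) {
      ord <- sample(nrow(refs))
      losses <- c(); accs <- c()
      for (s0 in seq(1L, length(ord), by = cfg$batch_size)) {
        sel <- ord[s0:min(s0 + cfg$batch_size - 1L, length(ord))]
        B <- length(sel)
        X <- matrix(0, B * N, 1)
        y <- integer(B * N)
        for (j in seq_len(B)) {
          vi <- refs[sel[j], "vol"]; pi <- refs[sel[j], "idx"]
          X[((j - 1) * N + 1):(j * N), 1] <- as.vector(
            get_patch(eps[[vi]]$padded, eps[[vi]]$offsets[pi, ], patch))
          y[((j - 1) * N + 1):(j * N)] <- as.vector(
            get_patch(lab_eps[[vi]]$padded, lab_eps[[vi]]$offsets[pi, ],
                      patch)) + 1L
        }
        fw <- unet_fwd(model, X, rep(patch, 3L), B, training = TRUE)
        model$state <- fw$state
        ce <- softmax_ce(fw$logits, y)
        grads <- unet_bwd(model, ce$dZ, fw, rep(patch, 3L), B)
        st <- sgd_step(model$params, grads, vel, cfg$learning_rate,
                       cfg$momentum, cfg$decay, cfg$nesterov, iter)
        model$params <- st$params; vel <- st$vel
        iter <- iter + 1
        losses <- c(losses, ce$loss); accs <- c(accs, ce$acc)
      }
      vd <- NA_real_
      if (length(vprep) && (ep_i %% cfg$val_freq == 0 || ep_i == cfg$epochs)) {
        vd <- mean(vapply(vprep, function(p) {
          epv <- extract_patches(p$img, patch, cfg$stride)
          pred <- unpad(predict_padded(model, epv), dim(p$img))
          dice(pred, p$lab, label_ids = seq_len(K - 1))$total
        }, numeric(1)))
        if (cfg$select_best && vd > best$dice) {
          best <- list(dice = vd, epoch = ep_i, params = model$params,
                       state = model$state)
        }
      }
      hist <- rbind(hist, data.frame(epoch = ep_i, loss = mean(losses),
                                     accuracy = mean(accs), val_dice = vd))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f acc %.4f val Dice %s", ep_i,
                        mean(losses), mean(accs),
                        ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
    }
  })
  if (cfg$select_best && !is.null(best$params)) {
    model$params <- best$params
    model$state <- best$state
    model$best_epoch <- best$epoch
  } else model$best_epoch <- cfg$epochs
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Segment a volume with a trained network
#'
#' Rescales the volume to the working shape, standardizes intensities,
#' extracts overlapping patches, forwards them through the network, fuses
#' the class scores of overlapping patches (average by default), takes the
#' voxel-wise argmax, removes the padding and rescales the labels (nearest
#' neighbour) back to the original grid. Deterministic given the weights.
#'
#' @param m a trained `unet_model`.
#' @param v a [volume3d()].
#' @param stride optional stride override for inference.
#' @return a [label_volume()] on the grid of `v`.
#' @export
predict_volume <- function(m, v, stride = NULL) {
  if (!isTRUE(m$trained)) stop("predict_volume: model is not trained")
  cfg <- m$cfg
  if (!is.null(stride)) cfg$stride <- as.integer(stride)
  arr <- as_vol_array(v)
  orig <- dim(arr)
  p <- prep_pair(v, NULL, cfg)
  m$cfg <- cfg
  ep <- extract_patches(p$img, cfg$patch_size, cfg$stride)
  lab <- unpad(predict_padded(m, ep), cfg$scaled_shape)
  if (!identical(orig, cfg$scaled_shape))
    lab <- resize_array(lab, orig, "nearest")
  labs <- if (cfg$n_labels == 7) neuropil_labels()
          else data.frame(id = seq_len(cfg$n_labels - 1),
                          name = paste0("L", seq_len(cfg$n_labels - 1)),
                          paired = FALSE)
  spacing <- if (inherits(v, "volume3d")) v$spacing_mm else 1
  label_volume(lab, labs, spacing)
}

#' Fine-tune the encoder on a new dataset
#'
#' Transfer learning across species: the decoder weights are frozen and only
#' the encoder is optimized on the new data (useful when few labelled
#' volumes of the new species exist).
#'
#' @param m a trained `unet_model`.
#' @param train,val pairs as in [train_unet()].
#' @param cfg optional `net_config` overriding the training schedule; the
#'   architecture fields must match the original model.
#' @return fine-tuned `unet_model`; its history carries the trainable
#'   parameter count.
#' @export
finetune_encoder <- function(m, train, val = list(), cfg = NULL) {
  if (!isTRUE(m$trained)) stop("finetune_encoder: model is not trained")
  if (length(train) < 1) stop("finetune_encoder: need at least one new pair")
  if (is.null(cfg)) cfg <- m$cfg
  for (f in c("patch_size", "base_channels", "max_channels", "n_labels"))
    if (!identical(cfg[[f]], m$cfg[[f]]))
      stop("finetune_encoder: architecture field ", f, " must match the model")
  K <- cfg$n_labels
  for (p in train) {
    ids <- unique(as.vector(as_vol_array(p$labels)))
    if (any(ids < 0 | ids >= K))
      stop("finetune_encoder: label id outside 0..", K - 1)
  }
  mask <- lapply(names(m$params), function(nm) grepl("^enc", nm))
  names(mask) <- names(m$params)

  prep <- lapply(train, function(p) prep_pair(p$image, p$labels, cfg))
  vprep <- lapply(val, function(p) prep_pair(p$image, p$labels, cfg))
  patch <- cfg$patch_size; N <- patch^3
  eps <- lapply(prep, function(p) extract_patches(p$img, patch, cfg$stride))
  lab_eps <- lapply(prep, function(p) extract_patches(p$lab, patch, cfg$stride))
  refs <- do.call(rbind, lapply(seq_along(eps), function(vi)
    cbind(vol = vi, idx = seq_len(nrow(eps[[vi]]$offsets)))))

  model <- m
  model$cfg <- cfg
  vel <- zeros_like(model$params)
  iter <- 0
  best <- list(dice = -Inf, epoch = NA_integer_, params = NULL, state = NULL)
  hist <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric(),
                     val_dice = numeric())
  with_seed(cfg$seed + 2L, {
    for (ep_i in seq_len(cfg$epochs)) {
      ord <- sample(nrow(refs))
      losses <- c(); accs <- c()
      for (s0 in seq(1L, length(ord), by = cfg$batch_size)) {
        sel <- ord[s0:min(s0 + cfg$batch_size - 1L, length(ord))]
        B <- length(sel)
        X <- matrix(0, B * N, 1); y <- integer(B * N)
        for (j in seq_len(B)) {
          vi <- refs[sel[j], "vol"]; pi <- refs[sel[j], "idx"]
          X[((j - 1) * N + 1):(j * N), 1] <- as.vector(
            get_patch(eps[[vi]]$padded, eps[[vi]]$offsets[pi, ], patch))
          y[((j - 1) * N + 1):(j * N)] <- as.vector(
            get_patch(lab_eps[[vi]]$padded, lab_eps[[vi]]$offsets[pi, ],
                      patch)) + 1L
        }
        fw <- unet_fwd(model, X, rep(patch, 3L), B, training = TRUE)
        # freeze decoder/head batch-norm running statistics as well
        for (nm in names(fw$state))
          if (grepl("^enc", nm)) model$state[[nm]] <- fw$state[[nm]]
        ce <- softmax_ce(fw$logits, y)
        grads <- unet_bwd(model, ce$dZ, fw, rep(patch, 3L), B)
        st <- sgd_step(model$params, grads, vel, cfg$learning_rate,
                       cfg$momentum, cfg$decay, cfg$nesterov, iter,
                       mask = mask)
        model$params <- st$params; vel <- st$vel
        iter <- iter + 1
        losses <- c(losses, ce$loss); accs <- c(accs, ce$acc)
      }
      vd <- NA_real_
      if (length(vprep) && (ep_i %% cfg$val_freq == 0 || ep_i == cfg$epochs)) {
        vd <- mean(vapply(vprep, function(p) {
          epv <- extract_patches(p$img, patch, cfg$stride)
          pred <- unpad(predict_padded(model, epv), dim(p$img))
          dice(pred, p$lab, label_ids = seq_len(K - 1))$total
        }, numeric(1)))
        if (cfg$select_best && vd > best$dice)
          best <- list(dice = vd, epoch = ep_i, params = model$params,
                       state = model$state)
      }
      hist <- rbind(hist, data.frame(epoch = ep_i, loss = mean(losses),
                                     accuracy = mean(accs), val_dice = vd))
    }
  })
  if (cfg$select_best && !is.null(best$params)) {
    model$params <- best$params; model$state <- best$state
    model$best_epoch <- best$epoch
  } else model$best_epoch <- cfg$epochs
  attr(hist, "trainable_parameters") <- n_parameters(model, encoder_only = TRUE)
  attr(hist, "total_parameters") <- n_parameters(model)
  model$history <- hist
  model
}

#' Segmentation accuracy as a function of training-set size
#'
#' For each `k` trains a network from scratch on the first `k` pool pairs
#' and evaluates mean total Dice and ASSD on the test pairs; mirrors the
#' rising-then-plateauing accuracy observed when the number of 3D training
#' images is increased.
#'
#' @param pool list of training pairs (ordered; first `k` are used).
#' @param k_values training-set sizes; `max(k) <= length(pool)`.
#' @param val,test validation and test pairs.
#' @param cfg a [net_config()].
#' @param path optional CSV output path.
#' @return data.frame with columns `k`, `dice`, `assd`.
#' @export
learning_curve <- function(pool, k_values, val, test,
                           cfg = net_profile("micro"), path = NULL) {
  if (any(k_values < 1)) stop("learning_curve: k values must be >= 1")
  if (max(k_values) > length(pool))
    stop("learning_curve: max(k) exceeds pool size")
  if (length(test) == 0) stop("learning_curve: test set is empty")
  rows <- lapply(k_values, function(k) {
    m <- train_unet(pool[seq_len(k)], val, cfg)
    evs <- lapply(test, function(p) {
      pred <- predict_volume(m, p$image)
      evaluate_segmentation(pred, p$labels)
    })
    data.frame(k = k,
               dice = mean(vapply(evs, `[[`, numeric(1), "total_dice")),
               assd = mean(vapply(evs, `[[`, numeric(1), "total_assd")))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
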