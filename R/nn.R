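# Minimal dense-tensor neural-network kernels.
#
# Activations are stored as (rows = batch*voxels, cols = channels) matrices,
# with the voxels of each sample forming a contiguous block of rows in
# column-major (z, y, x) order. A 3x3x3 convolution is an im2col gather
# (C++) followed by one BLAS GEMM; out-of-volume neighbours read as zeros,
# which realises zero padding, and the im2col adjoint (the same gathers with
# negated offsets) backpropagates to the input.

.nn_cache <- new.env(parent = emptyenv())

nn_coords <- function(shape) {
  d1 <- shape[1]; d2 <- shape[2]; d3 <- shape[3]
  list(
    i = rep(seq_len(d1), times = d2 * d3),
    j = rep(rep(seq_len(d2), each = d1), times = d3),
    k = rep(seq_len(d3), each = d1 * d2)
  )
}

# pooling child table: (N_out x prod(factors)) matrix of input linear indices
pool_table <- function(shape, factors, batch) {
  key <- paste0("pool:", paste(shape, collapse = "x"), ":",
                paste(factors, collapse = "x"), ":", batch)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  d <- shape; f <- factors
  if (any(d %% f != 0)) stop("pool_table: shape not divisible by pool factors")
  do <- d %/% f
  No <- prod(do)
  co <- nn_coords(do)
  cols <- expand.grid(a1 = seq_len(f[1]), a2 = seq_len(f[2]), a3 = seq_len(f[3]))
  child <- matrix(0L, No, nrow(cols))
  for (c_ in seq_len(nrow(cols))) {
    ii <- (co$i - 1L) * f[1] + cols$a1[c_]
    jj <- (co$j - 1L) * f[2] + cols$a2[c_]
    kk <- (co$k - 1L) * f[3] + cols$a3[c_]
    child[, c_] <- ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2]
  }
  if (batch > 1L) {
    N <- prod(d)
    child <- do.call(rbind, lapply(seq_len(batch) - 1L,
                                   function(b) child + b * N))
  }
  .nn_cache[[key]] <- child
  child
}

# nearest-neighbour upsample parent table: fine voxel -> coarse voxel row
upsample_table <- function(coarse_shape, factors, batch) {
  key <- paste0("up:", paste(coarse_shape, collapse = "x"), ":",
                paste(factors, collapse = "x"), ":", batch)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  d <- coarse_shape; f <- factors
  fine <- d * f
  co <- nn_coords(fine)
  ii <- (co$i - 1L) %/% f[1] + 1L
  jj <- (co$j - 1L) %/% f[2] + 1L
  kk <- (co$k - 1L) %/% f[3] + 1L
  p <- ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2]
  if (batch > 1L) {
    Nc <- prod(d); Nf <- prod(fine)
    p <- unlist(lapply(seq_len(batch) - 1L, function(b) p + b * Nc))
  }
  .nn_cache[[key]] <- p
  p
}

# Convolution via im2col: the (batch*N) x (27*Cin) neighbourhood matrix is
# built once in C++ and the whole convolution is a single GEMM. The column
# blocks are offset-major, matching the weight layout (27*Cin x Cout).
# Weight row order: offset o (first axis fastest), then input channel.
conv_fwd <- function(X, W, shape, batch) {
  col <- .im2col_cpp(X, as.integer(shape), as.integer(batch))
  list(Y = col %*% W, col = col)
}

conv_bwd <- function(col, dY, W, shape, batch, need_dX = TRUE) {
  Cin <- nrow(W) %/% 27L
  dW <- crossprod(col, dY)
  dX <- if (need_dX)
    .col2im_cpp(tcrossprod(dY, W), as.integer(shape), as.integer(batch), Cin)
  else NULL
  list(dX = dX, dW = dW)
}

bn_fwd <- function(X, gamma, beta, run_mean, run_var, training,
                   momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc * xc)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- sweep(X, 2, mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invstd, `*`)
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(Y = Y, xhat = xhat, invstd = invstd,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`)
  dX <- sweep(dX, 2, cache$invstd, `*`)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(X, child) {
  M <- X[child[, 1], , drop = FALSE]
  arg <- matrix(1L, nrow(M), ncol(M))
  for (c_ in 2:ncol(child)) {
    G <- X[child[, c_], , drop = FALSE]
    upd <- G > M
    M[upd] <- G[upd]
    arg[upd] <- c_
  }
  list(Y = M, arg = arg)
}

pool_bwd <- function(dY, cache, child, n_in) {
  dX <- matrix(0, n_in, ncol(dY))
  arg <- cache$arg
  No <- nrow(dY)
  for (c_ in seq_len(ncol(child))) {
    sel <- which(arg == c_)
    if (!length(sel)) next
    r <- ((sel - 1L) %% No) + 1L
    ch <- ((sel - 1L) %/% No) + 1L
    dX[cbind(child[r, c_], ch)] <- dY[sel]
  }
  dX
}

upsample_fwd <- function(X, parent) X[parent, , drop = FALSE]

upsample_bwd <- function(dY, parent, n_coarse) {
  out <- rowsum(dY, parent)
  # rowsum drops absent groups; with exact factor upsampling every coarse
  # voxel is a parent, so rows are 1..n_coarse in order
  stopifnot(nrow(out) == n_coarse)
  out
}

softmax_rows <- function(Z) {
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  P <- exp(Z - mx)
  P / rowSums(P)
}

# cross-entropy loss over rows; y is an integer class vector (1-based)
softmax_ce <- function(Z, y) {
  P <- softmax_rows(Z)
  n <- nrow(Z)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(n), y)] + eps))
  dZ <- P
  dZ[cbind(seq_len(n), y)] <- dZ[cbind(seq_len(n), y)] - 1
  dZ <- dZ / n
  acc <- mean(max.col(P, ties.method = "first") == y)
  list(loss = loss, dZ = dZ, acc = acc)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# SGD with momentum, Nesterov momentum and inverse-time learning-rate decay
# (lr_t = lr / (1 + decay * iteration)).
sgd_step <- function(params, grads, vel, lr, momentum, decay, nesterov, iter,
                     mask = NULL) {
  lr_t <- lr / (1 + decay * iter)
  for (nm in names(grads)) {
    if (!is.null(mask) && !mask[[nm]]) next
    g <- grads[[nm]]
    v <- momentum * vel[[nm]] - lr_t * g
    vel[[nm]] <- v
    params[[nm]] <- params[[nm]] + if (nesterov) momentum * v - lr_t * g else v
  }
  list(params = params, vel = vel)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-7, iter, mask = NULL) {
  for (nm in names(grads)) {
    if (!is.null(mask) && !mask[[nm]]) next
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^iter)
    vhat <- state$v[[nm]] / (1 - b2^iter)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

zeros_like <- function(params) lapply(params, function(p) p * 0)
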