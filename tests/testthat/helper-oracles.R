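# Independent brute-force oracles, deliberately written with naive loops and
# base-R primitives so that they share no code with the implementation.

# mean filter with reflect padding (edge slice duplicated), direct 27-term sum
brute_mean3 <- function(arr) {
  d <- dim(arr)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    s <- 0
    for (ok in -1:1) for (oj in -1:1) for (oi in -1:1)
      s <- s + arr[refl(i + oi, d[1]), refl(j + oj, d[2]), refl(k + ok, d[3])]
    out[i, j, k] <- s / 27
  }
  out
}

brute_dice <- function(A, B, ids) {
  per <- sapply(ids, function(i) {
    na <- sum(A == i); nb <- sum(B == i)
    if (na + nb == 0) return(1)
    2 * sum(A == i & B == i) / (na + nb)
  })
  inter <- sum(sapply(ids, function(i) sum(A == i & B == i)))
  den <- sum(A %in% ids) + sum(B %in% ids)
  list(per_label = per, total = if (den == 0) 1 else 2 * inter / den)
}

# surface voxels: labelled voxel with a face neighbour outside the label or
# on the array border
brute_surface <- function(A, i) {
  d <- dim(A)
  idx <- which(A == i, arr.ind = TRUE)
  if (nrow(idx) == 0) return(idx)
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    surf <- FALSE
    for (ax in 1:3) for (s in c(-1, 1)) {
      w <- v; w[ax] <- w[ax] + s
      if (w[ax] < 1 || w[ax] > d[ax] || A[w[1], w[2], w[3]] != i) surf <- TRUE
    }
    keep[r] <- surf
  }
  idx[keep, , drop = FALSE]
}

# all-pairs symmetric surface distance for one label
brute_assd_label <- function(A, B, i) {
  Sa <- brute_surface(A, i); Sb <- brute_surface(B, i)
  if (nrow(Sa) == 0 && nrow(Sb) == 0) return(list(sum = 0, n = 0))
  if (nrow(Sa) == 0 || nrow(Sb) == 0) return(list(sum = NA_real_, n = NA))
  D <- as.matrix(dist(rbind(Sa, Sb)))
  D <- D[seq_len(nrow(Sa)), nrow(Sa) + seq_len(nrow(Sb)), drop = FALSE]
  list(sum = sum(apply(D, 1, min)) + sum(apply(D, 2, min)),
       n = nrow(Sa) + nrow(Sb))
}

brute_assd <- function(A, B, ids) {
  parts <- lapply(ids, function(i) brute_assd_label(A, B, i))
  per <- sapply(parts, function(p)
    if (is.na(p$sum)) NA_real_ else if (p$n == 0) 0 else p$sum / p$n)
  ok <- !is.na(per) & sapply(parts, function(p) !identical(p$n, 0))
  tot_n <- sum(unlist(lapply(parts[ok], `[[`, "n")))
  tot <- if (tot_n == 0) 0 else
    sum(unlist(lapply(parts[ok], `[[`, "sum"))) / tot_n
  list(per_label = per, total = tot)
}

random_label_pair <- function(dmax = 12, k = 3, seed = 1) {
  set.seed(seed)
  d <- sample(4:dmax, 3, replace = TRUE)
  # correlated random fields give labels with coherent blobs and overlaps
  A <- array(sample(0:k, prod(d), replace = TRUE), d)
  B <- A
  flip <- runif(prod(d)) < 0.3
  B[flip] <- sample(0:k, sum(flip), replace = TRUE)
  list(A = A, B = B, ids = seq_len(k))
}
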