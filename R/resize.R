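# Array resizing used to bring volumes to the network's working shape:
# trilinear interpolation for images, nearest neighbour for labels.
# Both are separable and implemented as per-axis matrix products with the
# half-pixel sampling convention in_pos = (out_i + 0.5) * n_in/n_out - 0.5.

axis_weights <- function(n_in, n_out, method) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5  # 1-based continuous pos
  if (method == "nearest") {
    idx <- pmin(n_in, pmax(1L, round(pos)))
    # round() half-to-even can pick either neighbour at exact .5; use floor+1/2
    idx <- pmin(n_in, pmax(1L, floor(pos + 0.5)))
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), idx)] <- 1
  } else {
    lo <- floor(pos)
    frac <- pos - lo
    lo <- pmin(n_in, pmax(1L, lo))
    hi <- pmin(n_in, lo + 1)
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), lo)] <- W[cbind(seq_len(n_out), lo)] + (1 - frac)
    W[cbind(seq_len(n_out), hi)] <- W[cbind(seq_len(n_out), hi)] + frac
  }
  W
}

#' Resize a 3D array
#'
#' @param arr 3D array (z, y, x).
#' @param out_dim target dimensions, length 3.
#' @param method `"trilinear"` (images) or `"nearest"` (labels).
#' @return resized array.
#' @export
resize_array <- function(arr, out_dim, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  out_dim <- as.integer(out_dim)
  if (identical(d, out_dim)) return(arr)
  apply_axis1 <- function(a, n_out) {
    W <- axis_weights(dim(a)[1], n_out, method)
    array(W %*% matrix(a, dim(a)[1]), c(n_out, dim(a)[2], dim(a)[3]))
  }
  is_int <- is.integer(arr)
  arr <- apply_axis1(arr, out_dim[1])
  arr <- aperm(apply_axis1(aperm(arr, c(2, 1, 3)), out_dim[2]), c(2, 1, 3))
  arr <- aperm(apply_axis1(aperm(arr, c(3, 2, 1)), out_dim[3]), c(3, 2, 1))
  if (is_int && method == "nearest") storage.mode(arr) <- "integer"
  arr
}

#' @rdname resize_array
#' @param v a [volume3d()] or [label_volume()]; spacing is rescaled by the
#'   axis-wise mean shrink factor to keep physical extent comparable.
#' @export
resize_volume <- function(v, out_dim) {
  if (inherits(v, "label_volume")) {
    out <- resize_array(v$data, out_dim, "nearest")
    label_volume(out, v$labels, v$spacing_mm * mean(dim(v$data) / out_dim))
  } else if (inherits(v, "volume3d")) {
    out <- resize_array(v$data, out_dim, "trilinear")
    volume3d(out, v$spacing_mm * mean(dim(v$data) / out_dim), v$flipped_z)
  } else resize_array(v, out_dim)
}
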