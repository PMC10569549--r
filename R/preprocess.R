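#' Arithmetic mean denoising filter
#'
#' Replaces every voxel by the arithmetic mean of its 3x3x3 neighbourhood,
#' the standard light denoising step applied to stained micro-CT volumes
#' before interpolation or training. Borders are handled by reflect padding
#' (edge slice duplicated), so the output has the same shape and spacing.
#' The operator is linear and its output values stay within the input range.
#'
#' @param v a [volume3d()] (or bare 3D array).
#' @return the filtered volume, same class as the input.
#' @export
denoise_mean3 <- function(v) {
  arr <- as_vol_array(v)
  stopifnot(length(dim(arr)) == 3, length(arr) > 0)
  out <- array(.mean3_cpp(as.numeric(arr), dim(arr)), dim(arr))
  if (inherits(v, "volume3d")) volume3d(out, v$spacing_mm, v$flipped_z) else out
}

#' Standardize volume intensities
#'
#' Affine rescaling so that the output has mean `ref_mean` and variance
#' `ref_var` (defaults: zero mean, unit variance), matching the intensity
#' normalization applied to every volume before network training/inference.
#'
#' @param v a [volume3d()] or 3D array.
#' @param ref_mean,ref_var target mean and variance.
#' @return standardized volume, same class as the input.
#' @export
normalize_intensity <- function(v, ref_mean = 0, ref_var = 1) {
  arr <- as_vol_array(v)
  m <- mean(arr)
  s2 <- mean((arr - m)^2)
  if (s2 <= 0) stop("normalize_intensity: constant input has degenerate variance")
  out <- (arr - m) / sqrt(s2) * sqrt(ref_var) + ref_mean
  if (inherits(v, "volume3d")) volume3d(out, v$spacing_mm, v$flipped_z) else out
}

#' Flip a volume along the z axis
#'
#' Orientation normalization for specimens scanned upside down: reverses the
#' slice order on the first (z) array axis and toggles the orientation flag.
#' Applying the flip twice restores the original volume bit-exactly.
#'
#' @param v a [volume3d()], [label_volume()] or 3D array.
#' @return flipped volume of the same class.
#' @export
flip_z <- function(v) {
  arr <- as_vol_array(v)
  out <- arr[dim(arr)[1]:1, , , drop = FALSE]
  if (inherits(v, "volume3d"))
    volume3d(out, v$spacing_mm, flipped_z = !v$flipped_z)
  else if (inherits(v, "label_volume"))
    label_volume(out, v$labels, v$spacing_mm)
  else out
}

#' Crop a volume to a bounding box with a safety buffer
#'
#' Extracts the subvolume covering `bbox` expanded by `buffer` slices on
#' every side, clamped to the volume bounds. Spacing is preserved.
#'
#' @param v a [volume3d()], [label_volume()] or 3D array.
#' @param bbox 2x3 matrix (or list of 3 ranges): first/last index per axis
#'   (z, y, x), inclusive.
#' @param buffer number of extra slices added on every side before clamping.
#' @return cropped volume of the same class.
#' @export
crop_to_bbox <- function(v, bbox, buffer = 0) {
  arr <- as_vol_array(v)
  d <- dim(arr)
  if (is.list(bbox)) bbox <- vapply(bbox, range, numeric(2))
  bbox <- round(bbox)
  if (any(bbox[1, ] > bbox[2, ]) || any(bbox[2, ] < 1) || any(bbox[1, ] > d))
    stop("crop_to_bbox: empty or out-of-range bbox")
  lo <- pmax(1, bbox[1, ] - buffer)
  hi <- pmin(d, bbox[2, ] + buffer)
  out <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (inherits(v, "volume3d")) volume3d(out, v$spacing_mm, v$flipped_z)
  else if (inherits(v, "label_volume")) label_volume(out, v$labels, v$spacing_mm)
  else out
}

#' Bounding box of labelled foreground
#'
#' @param lv a [label_volume()] or integer array.
#' @return 2x3 matrix of first/last foreground indices per axis, or NULL if
#'   the volume has no foreground.
#' @export
foreground_bbox <- function(lv) {
  arr <- as_vol_array(lv)
  w <- which(arr != 0, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}
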