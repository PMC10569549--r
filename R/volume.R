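#' Neuropil label table
#'
#' The canonical label encoding used throughout the package: 0 is background,
#' 1..6 are the six neuropils analysed in comparative bee neuroanatomy.
#' The optic lobes (OL) are always derived as ME + LO and never stored as a
#' voxel label.
#'
#' @return A data.frame with columns `id`, `name` and `paired`.
#' @export
neuropil_labels <- function() {
  data.frame(
    id = 1:6,
    name = c("AL", "MB", "CX", "ME", "LO", "OTH"),
    paired = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' 3D grayscale volume
#'
#' A 3D scalar image with isotropic voxel spacing. Arrays are ordered
#' `(z, y, x)`; the anatomical left-right axis is the third array axis `x`,
#' and "left" means lower `x` indices.
#'
#' @param data numeric 3D array, ordered (z, y, x).
#' @param spacing_mm isotropic voxel edge length in millimetres.
#' @param flipped_z whether z-flip orientation normalization was applied.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing_mm = 1, flipped_z = FALSE) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("volume3d: data contains non-finite values")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0)
    stop("volume3d: spacing_mm must be a single positive number")
  structure(
    list(data = data, spacing_mm = spacing_mm, flipped_z = isTRUE(flipped_z)),
    class = "volume3d"
  )
}

#' Integer-labelled 3D volume
#'
#' Shares a voxel grid with a [volume3d()]; every voxel value must be 0
#' (background) or an id present in the label map.
#'
#' @param data integer 3D array, ordered (z, y, x).
#' @param labels label map data.frame with columns `id`, `name`, `paired`;
#'   defaults to [neuropil_labels()].
#' @param spacing_mm isotropic voxel edge length in millimetres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, labels = neuropil_labels(), spacing_mm = 1) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  ids <- sort(unique(as.vector(data)))
  bad <- setdiff(ids, c(0L, labels$id))
  if (length(bad))
    stop("label_volume: voxel values outside label map: ",
         paste(bad, collapse = ", "))
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0)
    stop("label_volume: spacing_mm must be a single positive number")
  structure(
    list(data = data, labels = labels, spacing_mm = spacing_mm),
    class = "label_volume"
  )
}

#' @exportS3Method print volume3d
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d (z,y,x), spacing %.4g mm, range [%.4g, %.4g]%s\n",
              d[1], d[2], d[3], x$spacing_mm, min(x$data), max(x$data),
              if (x$flipped_z) ", z-flipped" else ""))
  invisible(x)
}

#' @exportS3Method print label_volume
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  tab <- tabulate(x$data + 1L, nbins = max(x$labels$id) + 1L)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), spacing %.4g mm\n",
              d[1], d[2], d[3], x$spacing_mm))
  cat("  voxels:", paste(sprintf("%s=%d", c("bg", x$labels$name), tab),
                         collapse = " "), "\n")
  invisible(x)
}

as_vol_array <- function(v) {
  if (inherits(v, "volume3d") || inherits(v, "label_volume")) v$data else v
}
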