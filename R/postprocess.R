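#' Remove outlier islands from a segmentation
#'
#' For every label except those in `exclude`, computes the 26-connected
#' components of the label's voxels and relabels to background every
#' component smaller than `threshold` times the label's largest component.
#' The default threshold of 0.1 is deliberately low so that the smaller body
#' of a paired neuropil is never deleted (near-equal components have size
#' ratio close to 1), while detached misclassified specks are removed.
#' The central complex is excluded by default: it is small and fragmented
#' segmentations of it are better kept for manual review. Idempotent.
#'
#' @param lv a [label_volume()].
#' @param threshold fraction in (0, 1] of the largest component.
#' @param exclude character names (or integer ids) of labels to leave
#'   untouched; default `"CX"`.
#' @return cleaned [label_volume()].
#' @export
remove_islands <- function(lv, threshold = 0.1, exclude = "CX") {
  stopifnot(inherits(lv, "label_volume"))
  if (threshold <= 0 || threshold > 1)
    stop("remove_islands: threshold must be in (0, 1]")
  excl_ids <- if (is.character(exclude))
    lv$labels$id[lv$labels$name %in% exclude] else as.integer(exclude)
  arr <- lv$data
  d <- dim(arr)
  for (i in setdiff(lv$labels$id, excl_ids)) {
    mask <- arr == i
    if (!any(mask)) next
    cc <- .cc26_cpp(as.integer(mask), d)
    sizes <- attr(cc, "sizes")
    drop <- which(sizes < threshold * max(sizes))
    if (length(drop)) arr[array(cc %in% drop, d)] <- 0L
  }
  label_volume(arr, lv$labels, lv$spacing_mm)
}

#' Split paired neuropils into left and right sides
#'
#' The midline plane is placed at the voxel-count centroid (along the
#' left-right x axis) of all paired-label voxels, making the split robust to
#' off-centre crops. Each 26-connected component of a paired label is
#' assigned to the side containing its centroid ("left" = lower x). A label
#' consisting of a single component whose voxels span both sides by more
#' than `span_frac` each is flagged non-separable (its counts are withheld),
#' which is how midline-merged mushroom bodies present. Centroid ties
#' (exactly on the plane) are resolved by majority voxel side, then left,
#' with a warning.
#'
#' @param lv a [label_volume()].
#' @param paired label names to split; defaults to the paired labels of the
#'   label map.
#' @param span_frac bilateral span fraction above which a single component
#'   is considered merged.
#' @return data.frame with one row per paired label: voxel counts `left`,
#'   `right`, and logical `separable`.
#' @export
split_left_right <- function(lv, paired = NULL, span_frac = 0.05) {
  stopifnot(inherits(lv, "label_volume"))
  if (is.null(paired)) paired <- lv$labels$name[lv$labels$paired]
  ids <- lv$labels$id[match(paired, lv$labels$name)]
  if (any(is.na(ids)))
    stop("split_left_right: paired labels absent from label map: ",
         paste(paired[is.na(ids)], collapse = ", "))
  arr <- lv$data
  d <- dim(arr)
  x_of <- function(lin) ((lin - 1L) %/% (d[1] * d[2])) + 1L

  all_paired <- which(arr %in% ids)
  if (!length(all_paired)) {
    warning("split_left_right: no paired-label voxels present")
    return(data.frame(label = paired, left = 0L, right = 0L,
                      separable = FALSE, stringsAsFactors = FALSE))
  }
  midline <- mean(x_of(all_paired))

  out <- lapply(seq_along(ids), function(k) {
    i <- ids[k]
    vox <- which(arr == i)
    if (!length(vox)) {
      warning("split_left_right: label ", paired[k], " absent; zero counts")
      return(data.frame(label = paired[k], left = 0L, right = 0L,
                        separable = FALSE, stringsAsFactors = FALSE))
    }
    cc <- .cc26_cpp(as.integer(arr == i), d)
    ncomp <- length(attr(cc, "sizes"))
    xs <- x_of(vox)
    comp <- cc[vox]
    if (ncomp == 1) {
      fl <- mean(xs < midline)
      fr <- mean(xs > midline)
      if (fl > span_frac && fr > span_frac)
        return(data.frame(label = paired[k], left = NA_integer_,
                          right = NA_integer_, separable = FALSE,
                          stringsAsFactors = FALSE))
    }
    left <- 0L; right <- 0L
    for (c_ in seq_len(ncomp)) {
      cx <- xs[comp == c_]
      cen <- mean(cx)
      side <- if (cen < midline) "L" else if (cen > midline) "R" else {
        warning("split_left_right: component centroid of ", paired[k],
                " exactly on midline; assigning by majority voxel side")
        nl <- sum(cx < midline); nr <- sum(cx > midline)
        if (nl >= nr) "L" else "R"
      }
      if (side == "L") left <- left + length(cx) else right <- right + length(cx)
    }
    data.frame(label = paired[k], left = left, right = right,
               separable = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "midline_x") <- midline
  res
}

#' Measure neuropil volumes of a segmentation
#'
#' Volume of each label is its voxel count times the cubed voxel spacing
#' (mm^3). Derives the optic lobe volume OL = ME + LO, total brain volume as
#' the sum of the six neuropils, relative volumes (% of total over AL, MB,
#' OL, CX, OTH), and left/right volumes from a [split_left_right()] result.
#'
#' @param lv a [label_volume()].
#' @param sides optional result of [split_left_right()]; computed if NULL.
#' @param meta named list/row with specimen metadata (`specimen`, `species`,
#'   `population`, `hive`); missing entries become NA.
#' @return a one-row `specimen_record` data.frame.
#' @export
measure_volumes <- function(lv, sides = NULL, meta = list()) {
  stopifnot(inherits(lv, "label_volume"))
  if (is.null(sides)) sides <- split_left_right(lv)
  sp3 <- lv$spacing_mm^3
  counts <- tabulate(lv$data, nbins = max(lv$labels$id))
  vols <- counts[lv$labels$id] * sp3
  names(vols) <- lv$labels$name
  if (sum(vols) == 0) stop("measure_volumes: empty segmentation")
  rec <- data.frame(
    specimen = meta$specimen %||% NA_character_,
    species = meta$species %||% NA_character_,
    population = meta$population %||% NA_character_,
    hive = meta$hive %||% NA_character_,
    stringsAsFactors = FALSE
  )
  for (r in c("AL", "MB", "CX", "ME", "LO", "OTH")) rec[[r]] <- vols[[r]]
  rec$OL <- rec$ME + rec$LO
  rec$total <- sum(vols)
  for (r in c("AL", "MB", "ME", "LO")) {
    row <- sides[sides$label == r, ]
    if (nrow(row) == 1 && isTRUE(row$separable)) {
      rec[[paste0(r, "_left")]] <- row$left * sp3
      rec[[paste0(r, "_right")]] <- row$right * sp3
    } else {
      rec[[paste0(r, "_left")]] <- NA_real_
      rec[[paste0(r, "_right")]] <- NA_real_
    }
  }
  rec$OL_left <- rec$ME_left + rec$LO_left
  rec$OL_right <- rec$ME_right + rec$LO_right
  mb_row <- sides[sides$label == "MB", ]
  rec$mb_separable <- nrow(mb_row) == 1 && isTRUE(mb_row$separable)
  for (r in c("AL", "MB", "OL", "CX", "OTH"))
    rec[[paste0(r, "_rel")]] <- 100 * rec[[r]] / rec$total
  class(rec) <- c("specimen_record", class(rec))
  rec
}
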