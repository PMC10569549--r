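#' Dice similarity coefficient
#'
#' Per-label Dice `2|X_i ∩ X'_i| / (|X_i| + |X'_i|)` and the total Dice
#' `2 Σ_i |X_i ∩ X'_i| / (|X| + |X'|)`, where `|X|` counts the
#' non-background voxels of a segmentation (background is excluded from the
#' totals; including it would inflate scores towards 1 on mostly-empty
#' grids). A label empty in both segmentations scores 1 by convention and is
#' flagged in the result.
#'
#' @param a,b [label_volume()]s (or integer arrays) of identical shape.
#' @param label_ids integer label ids to evaluate; defaults to the label map
#'   of `a` or all non-zero values present.
#' @return list with `per_label` (named numeric), `total`, and
#'   `empty_labels` (labels empty on both sides).
#' @export
dice <- function(a, b, label_ids = NULL) {
  A <- as_vol_array(a); B <- as_vol_array(b)
  if (!identical(dim(A), dim(B)))
    stop("dice: volumes have different shapes")
  if (is.null(label_ids)) {
    label_ids <- if (inherits(a, "label_volume")) a$labels$id
                 else sort(setdiff(unique(c(A, B)), 0L))
  }
  per <- numeric(length(label_ids))
  names(per) <- as.character(label_ids)
  inter_sum <- 0
  empty <- integer(0)
  for (k in seq_along(label_ids)) {
    i <- label_ids[k]
    na <- sum(A == i); nb <- sum(B == i)
    inter <- sum(A == i & B == i)
    inter_sum <- inter_sum + inter
    if (na + nb == 0) {
      per[k] <- 1
      empty <- c(empty, i)
    } else per[k] <- 2 * inter / (na + nb)
  }
  total_den <- sum(A != 0) + sum(B != 0)
  total <- if (total_den == 0) 1 else 2 * inter_sum / total_den
  list(per_label = per, total = total, empty_labels = empty)
}

#' Average symmetric surface distance
#'
#' Surface voxels are labelled voxels with at least one face neighbour
#' outside the label (6-connectivity boundary test; array borders count as
#' boundary). For each label the nearest-surface Euclidean distances are
#' summed in both directions and divided by the total surface voxel count;
#' the total ASSD applies the same normalization over all labels. Distances
#' come from an exact Euclidean distance transform. A label with surface on
#' exactly one side has undefined distance: it is reported as `NA`, flagged,
#' and excluded from the total.
#'
#' @param a,b [label_volume()]s (or integer arrays) of identical shape and
#'   isotropic spacing.
#' @param label_ids labels to evaluate (default as in [dice()]).
#' @param spacing_mm voxel edge used for the mm-scale report; taken from `a`
#'   when it is a [label_volume()].
#' @return list with `per_label` (voxels), `per_label_mm`, `total`,
#'   `total_mm`, and `undefined_labels`.
#' @export
assd <- function(a, b, label_ids = NULL, spacing_mm = NULL) {
  A <- as_vol_array(a); B <- as_vol_array(b)
  if (!identical(dim(A), dim(B)))
    stop("assd: volumes have different shapes")
  if (is.null(spacing_mm))
    spacing_mm <- if (inherits(a, "label_volume")) a$spacing_mm else 1
  if (is.null(label_ids)) {
    label_ids <- if (inherits(a, "label_volume")) a$labels$id
                 else sort(setdiff(unique(c(A, B)), 0L))
  }
  d <- dim(A)
  storage.mode(A) <- "integer"; storage.mode(B) <- "integer"
  per <- numeric(length(label_ids)); names(per) <- as.character(label_ids)
  undef <- integer(0)
  sum_all <- 0; cnt_all <- 0
  for (k in seq_along(label_ids)) {
    i <- label_ids[k]
    Sa <- .surface6_cpp(A, d, as.integer(i))
    Sb <- .surface6_cpp(B, d, as.integer(i))
    na <- sum(Sa); nb <- sum(Sb)
    if (na == 0 && nb == 0) { per[k] <- 0; next }
    if (na == 0 || nb == 0) { per[k] <- NA_real_; undef <- c(undef, i); next }
    dist_to_b <- sqrt(.edt_sq_cpp(Sb, d))
    dist_to_a <- sqrt(.edt_sq_cpp(Sa, d))
    s <- sum(dist_to_b[Sa]) + sum(dist_to_a[Sb])
    per[k] <- s / (na + nb)
    sum_all <- sum_all + s; cnt_all <- cnt_all + na + nb
  }
  total <- if (cnt_all == 0) 0 else sum_all / cnt_all
  list(per_label = per, per_label_mm = per * spacing_mm,
       total = total, total_mm = total * spacing_mm,
       undefined_labels = undef)
}

#' Triage category of a segmentation error
#'
#' Converts a total Dice score into the manual-correction burden category:
#' error below 0.01% of Dice is `negligible` (little or no correction),
#' 0.01% to 4% is `slight` (a minute or two of manual correction), and
#' above 4% is `flawed` (extensive correction required).
#'
#' @param total_dice total Dice score in `[0, 1]`.
#' @return list with `error_pct` and `category`.
#' @export
error_category <- function(total_dice) {
  if (!is.numeric(total_dice) || is.na(total_dice) ||
      total_dice < 0 || total_dice > 1)
    stop("error_category: total_dice must be in [0, 1]")
  err <- (1 - total_dice) * 100
  cat <- if (err < 0.01) "negligible" else if (err <= 4) "slight" else "flawed"
  list(error_pct = err, category = cat)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Combines [dice()], [assd()] and [error_category()] into one record.
#'
#' @param pred,truth [label_volume()]s of identical shape.
#' @return An `eval_result` list: per-label and total Dice and ASSD
#'   (voxels and mm), error percentage and triage category.
#' @export
evaluate_segmentation <- function(pred, truth) {
  dc <- dice(pred, truth)
  as_ <- assd(pred, truth)
  ec <- error_category(dc$total)
  structure(
    list(dice = dc$per_label, total_dice = dc$total,
         assd = as_$per_label, assd_mm = as_$per_label_mm,
         total_assd = as_$total, total_assd_mm = as_$total_mm,
         error_pct = ec$error_pct, category = ec$category,
         empty_labels = dc$empty_labels,
         undefined_assd_labels = as_$undefined_labels),
    class = "eval_result"
  )
}

#' @exportS3Method print eval_result
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> total Dice %.4f (error %.2f%%, %s), total ASSD %.3f vox\n",
              x$total_dice, x$error_pct, x$category, x$total_assd))
  cat("  per-label Dice:",
      paste(sprintf("%s=%.3f", names(x$dice), x$dice), collapse = " "), "\n")
  invisible(x)
}
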