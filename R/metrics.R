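# Segmentation quality measures used to validate the pipeline against
# phantom ground truth.

#' Dice overlap per class
#'
#' `2|A n B| / (|A| + |B|)` between a predicted and a reference labeling,
#' computed for every class id present in the reference.
#'
#' @param pred,truth integer arrays of equal extent; voxels labeled `< 0`
#'   (unassigned) in `pred` count against the score.
#' @return named numeric vector of Dice coefficients, one per truth class.
#' @export
dice_score <- function(pred, truth) {
  classes <- sort(unique(as.integer(truth)))
  out <- vapply(classes, function(k) {
    a <- pred == k
    b <- truth == k
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
  names(out) <- classes
  out
}

#' Boundary recall of a partition against ground truth
#'
#' Fraction of ground-truth boundary voxels lying within `tol` voxels
#' (Euclidean) of a partition boundary voxel.
#'
#' @param labels partition label grid.
#' @param truth ground-truth label grid of the same extent.
#' @param tol tolerance in voxels.
#' @return scalar recall in `[0, 1]`.
#' @export
boundary_recall <- function(labels, truth, tol = 1) {
  gtb <- boundary_map(truth)
  if (!any(gtb)) return(1)
  pb <- boundary_map(labels)
  d2 <- edt_sq_cpp(as.logical(pb), as.integer(dim(pb)))
  mean(d2[gtb] <= tol^2)
}

#' Under-segmentation error of a partition
#'
#' For each region, the voxels not belonging to the region's dominant
#' ground-truth class are "leaked"; the error is total leakage over the
#' volume size.
#'
#' @inheritParams boundary_recall
#' @return scalar in `[0, 1]` (lower is better).
#' @export
undersegmentation_error <- function(labels, truth) {
  lab <- as.integer(labels)
  tr <- as.integer(truth)
  tr_dense <- match(tr, sort(unique(tr)))
  k <- max(lab)
  nt <- max(tr_dense)
  tab <- table(factor(lab, levels = seq_len(k)),
               factor(tr_dense, levels = seq_len(nt)))
  leaked <- sum(rowSums(tab) - apply(tab, 1, max))
  leaked / length(lab)
}
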