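# Segmentation accuracy metrics: Dice similarity coefficient, symmetric
# 95th-percentile Hausdorff distance over boundary voxel centres (mm), and
# signed/absolute volume difference percentage.

#' Dice similarity coefficient
#'
#' DSC = 2TP / (2TP + FP + FN) = 2|A intersect B| / (|A| + |B|). Two empty
#' masks are in perfect agreement by convention (DSC = 1); one empty and
#' one non-empty mask give 0.
#'
#' @param pred,truth [binary_mask()] objects on the same grid.
#' @return DSC in [0, 1].
#' @export
dice_coefficient <- function(pred, truth) {
  stopifnot(inherits(pred, "binary_mask"), inherits(truth, "binary_mask"))
  assert_same_grid(pred, truth)
  np <- sum(pred$data); nt <- sum(truth$data)
  if (np == 0L && nt == 0L) return(1.0)
  2 * sum(pred$data & truth$data) / (np + nt)
}

# Directed nearest-neighbour distances (mm) from each row of `a` to the
# point set `b`; coordinates are voxel indices, scaled by spacing. Chunked
# all-pairs evaluation keeps memory bounded on large boundaries.
.directed_min_dists <- function(a, b, spacing, chunk = 2048L) {
  a <- sweep(a, 2L, spacing, "*")
  b <- sweep(b, 2L, spacing, "*")
  bsq <- rowSums(b^2)
  n <- nrow(a)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    ach <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ach^2), bsq, "+") - 2 * tcrossprod(ach, b)
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' 95th-percentile Hausdorff distance
#'
#' Symmetric HD95: boundary voxels (6-connectivity) are extracted from both
#' masks, nearest-neighbour Euclidean distances between voxel centres are
#' computed in mm in both directions, and the larger of the two 95th
#' percentiles (linear interpolation over the sorted distances) is
#' returned. Identical masks give 0; the metric is undefined when either
#' mask is empty.
#'
#' @param pred,truth [binary_mask()] objects on the same grid, non-empty.
#' @param probs Percentile in (0, 1]; 0.95 by default, 1 gives the exact
#'   Hausdorff distance.
#' @return Distance in mm.
#' @export
hd95 <- function(pred, truth, probs = 0.95) {
  stopifnot(inherits(pred, "binary_mask"), inherits(truth, "binary_mask"))
  assert_same_grid(pred, truth)
  if (sum(pred$data) == 0L || sum(truth$data) == 0L)
    stop("HD95 undefined for empty mask")
  bp <- boundary_voxels(pred)
  bt <- boundary_voxels(truth)
  dp <- .directed_min_dists(bp, bt, pred$spacing)
  dt <- .directed_min_dists(bt, bp, pred$spacing)
  max(stats::quantile(dp, probs, names = FALSE, type = 7),
      stats::quantile(dt, probs, names = FALSE, type = 7))
}

#' Volume difference percentage
#'
#' VD% = 100 (V_pred - V_true) / V_true. Returned both signed (negative
#' means under-segmentation) and as an absolute magnitude, since published
#' tables typically report the magnitude.
#'
#' @param vol_pred_ml,vol_true_ml Volumes in ml; `vol_true_ml` must be > 0.
#' @return List with `signed` and `absolute` percentages.
#' @export
vd_pct <- function(vol_pred_ml, vol_true_ml) {
  if (vol_true_ml <= 0) stop("VD% undefined: ground-truth volume must be > 0")
  s <- 100 * (vol_pred_ml - vol_true_ml) / vol_true_ml
  list(signed = s, absolute = abs(s))
}

#' Full metrics report for a predicted/ground-truth mask pair
#'
#' @param pred,truth [binary_mask()] objects on the same grid.
#' @return An object of class `cp_metrics`: `dsc`, `hd95_mm`,
#'   `vd_pct_signed`, `vd_pct_abs`, `vol_pred_ml`, `vol_true_ml`.
#' @export
metrics_report <- function(pred, truth) {
  assert_same_grid(pred, truth)
  vp <- volume_ml(pred); vt <- volume_ml(truth)
  vd <- if (vt > 0) vd_pct(vp, vt) else list(signed = NA_real_,
                                             absolute = NA_real_)
  h <- if (sum(pred$data) > 0L && sum(truth$data) > 0L) hd95(pred, truth)
       else NA_real_
  structure(
    list(dsc = dice_coefficient(pred, truth), hd95_mm = h,
         vd_pct_signed = vd$signed, vd_pct_abs = vd$absolute,
         vol_pred_ml = vp, vol_true_ml = vt),
    class = "cp_metrics"
  )
}

#' @export
print.cp_metrics <- function(x, ...) {
  cat("Segmentation accuracy vs ground truth\n")
  cat(sprintf("  DSC:        %.4f\n", x$dsc))
  cat(sprintf("  HD95:       %s mm\n",
              if (is.na(x$hd95_mm)) "NA (empty mask)"
              else sprintf("%.3f", x$hd95_mm)))
  cat(sprintf("  VD%%:        %+.2f (|VD%%| = %.2f)\n",
              x$vd_pct_signed, x$vd_pct_abs))
  cat(sprintf("  volumes:    pred %.4f ml, truth %.4f ml\n",
              x$vol_pred_ml, x$vol_true_ml))
  invisible(x)
}
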