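# Binary morphology on 3-D masks. Implemented with logical array shifts:
# for the small structuring elements used here (radius 1-2) this is both
# exact and fast, and voxels outside the grid always count as background.

#' Spherical structuring element offsets
#'
#' Returns the integer voxel offsets of a digital ball: all (i, j, k) with
#' i^2 + j^2 + k^2 <= radius^2. For `radius = 1` this is the 6-connected
#' cross (centre plus face neighbours). A `"box"` shape gives the Chebyshev
#' ball (26-connectivity at radius 1) as an alternative reading of a
#' one-voxel kernel.
#'
#' @param radius Positive integer radius in voxels.
#' @param shape `"sphere"` (Euclidean ball, default) or `"box"`.
#' @return Integer matrix with one offset per row and columns (i, j, k).
#' @export
structuring_element <- function(radius = 1L, shape = c("sphere", "box")) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 1L) stop("structuring element radius must be >= 1 voxel")
  r <- -radius:radius
  off <- as.matrix(expand.grid(i = r, j = r, k = r))
  if (shape == "sphere")
    off <- off[rowSums(off^2) <= radius^2, , drop = FALSE]
  storage.mode(off) <- "integer"
  off
}

# Shift a logical array by an integer offset, filling exposed planes with
# `fill`. shift_array(x, c(1,0,0))[i,,] == x[i-1,,].
.shift_array <- function(x, offset, fill = FALSE) {
  d <- dim(x)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- offset[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      dst[[a]] <- (1 + o):d[a]
      src[[a]] <- 1:(d[a] - o)
    } else {
      dst[[a]] <- 1:(d[a] + o)
      src[[a]] <- (1 - o):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Erode a binary mask
#'
#' Morphological erosion: a voxel survives only if every offset of the
#' structuring element lands on a foreground voxel, with out-of-grid
#' positions counting as background. The default element is the radius-1
#' Euclidean ball ("eroded by one voxel using a sphere kernel").
#'
#' @param mask A [binary_mask()].
#' @param elem Offset matrix from [structuring_element()].
#' @return The eroded [binary_mask()]; always a subset of the input.
#' @export
erode_mask <- function(mask, elem = structuring_element(1L)) {
  stopifnot(inherits(mask, "binary_mask"))
  out <- mask$data
  for (r in seq_len(nrow(elem))) {
    o <- elem[r, ]
    if (all(o == 0L)) next
    # voxel v has neighbour v + o inside the mask  <=>  shift(mask, -o)[v]
    out <- out & .shift_array(mask$data, -o, fill = FALSE)
    if (!any(out)) break
  }
  binary_mask(out, mask$spacing, mask$affine)
}

#' Dilate a binary mask
#'
#' Morphological dilation with the given structuring element (used by the
#' phantom generator to build deliberately imperfect prior label maps).
#'
#' @inheritParams erode_mask
#' @return The dilated [binary_mask()]; always a superset of the input.
#' @export
dilate_mask <- function(mask, elem = structuring_element(1L)) {
  stopifnot(inherits(mask, "binary_mask"))
  out <- mask$data
  for (r in seq_len(nrow(elem))) {
    o <- elem[r, ]
    if (all(o == 0L)) next
    out <- out | .shift_array(mask$data, o, fill = FALSE)
  }
  binary_mask(out, mask$spacing, mask$affine)
}

#' Merge lateral-ventricle and choroid-plexus labels into a prior region
#'
#' Builds the per-hemisphere anatomical prior: the union of the lateral
#' ventricle and choroid plexus labels of one side. An empty region raises a
#' warning (typically a missing hemisphere in the parcellation), not an
#' error; the pipeline decides whether to proceed.
#'
#' @param labels A [label_volume()].
#' @param hemi A hemisphere label set from [hemisphere_labels()].
#' @return A [binary_mask()] true where the label is `lv` or `cp`.
#' @export
merge_region <- function(labels, hemi) {
  stopifnot(inherits(labels, "label_volume"))
  m <- labels$data == hemi$lv | labels$data == hemi$cp
  if (!any(m))
    warning("empty prior region for ", hemi$side,
            " hemisphere (labels ", hemi$lv, ", ", hemi$cp, ")")
  binary_mask(m, labels$spacing, labels$affine)
}

#' Hemisphere label identifiers
#'
#' Default integer IDs follow the FreeSurfer color lookup table: lateral
#' ventricle 4 (left) / 43 (right), choroid plexus 31 (left) / 63 (right).
#'
#' @param side `"left"` or `"right"`.
#' @param lv,cp Integer label IDs overriding the FreeSurfer defaults.
#' @return A list with fields `side`, `lv`, `cp`.
#' @export
hemisphere_labels <- function(side = c("left", "right"), lv = NULL, cp = NULL) {
  side <- match.arg(side)
  defaults <- list(left = c(lv = 4L, cp = 31L), right = c(lv = 43L, cp = 63L))
  lv <- if (is.null(lv)) defaults[[side]]["lv"] else as.integer(lv)
  cp <- if (is.null(cp)) defaults[[side]]["cp"] else as.integer(cp)
  if (lv <= 0 || cp <= 0 || lv == cp)
    stop("hemisphere labels must be positive and distinct")
  list(side = side, lv = unname(lv), cp = unname(cp))
}

#' Boundary voxels of a mask
#'
#' A foreground voxel is a boundary voxel if at least one of its six face
#' neighbours is background (out-of-grid counts as background). Used for the
#' 95th-percentile Hausdorff distance.
#'
#' @param mask A [binary_mask()].
#' @return Integer matrix of boundary voxel coordinates (one per row).
#' @export
boundary_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  interior <- erode_mask(mask, structuring_element(1L, "sphere"))
  which(mask$data & !interior$data, arr.ind = TRUE)
}
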