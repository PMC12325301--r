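# Intensity preprocessing inside the prior region: masked Gaussian
# smoothing followed by normalization to the non-zero voxel mean. The
# normalized 1-D samples are what the mixture model fits.

# Discrete Gaussian kernel, half-width 3*sigma (at least 1), normalized.
.gauss_kernel <- function(sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  d <- -h:h
  k <- exp(-d^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 1-D convolution along one axis with zero padding.
.conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  h <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim = d)
  for (t in seq_along(kernel)) {
    o <- integer(3)
    o[axis] <- t - h - 1L
    w <- kernel[t]
    if (w == 0) next
    out <- out + w * .shift_num(arr, o)
  }
  out
}

.shift_num <- function(x, offset) {
  d <- dim(x)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- offset[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      dst[[a]] <- (1 + o):d[a]; src[[a]] <- 1:(d[a] - o)
    } else {
      dst[[a]] <- 1:(d[a] + o); src[[a]] <- (1 - o):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

.conv3_separable <- function(arr, kernel) {
  for (axis in 1:3) arr <- .conv_axis(arr, kernel, axis)
  arr
}

#' Gaussian smoothing of an intensity volume
#'
#' 3-D Gaussian filtering with a separable discrete kernel, in voxel units.
#' With a `domain` mask the filter is mask-normalized: background voxels
#' contribute neither signal nor weight, so a constant image restricted to
#' any mask stays exactly constant and dark extra-regional tissue cannot
#' leak into region boundary voxels. `sigma = 0` returns the input
#' unchanged.
#'
#' @param volume An [intensity_volume()].
#' @param sigma Gaussian standard deviation in voxels (>= 0).
#' @param domain Optional [binary_mask()] restricting the filter support;
#'   voxels outside keep their input value.
#' @return A smoothed [intensity_volume()].
#' @export
smooth_volume <- function(volume, sigma = 0.5, domain = NULL) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (sigma < 0) stop("smoothing sigma must be >= 0")
  if (sigma == 0) return(volume)
  k <- .gauss_kernel(sigma)
  if (is.null(domain)) {
    out <- .conv3_separable(volume$data, k)
  } else {
    assert_same_grid(volume, domain)
    w <- array(as.numeric(domain$data), dim = dim(domain$data))
    num <- .conv3_separable(volume$data * w, k)
    den <- .conv3_separable(w, k)
    out <- volume$data
    inside <- domain$data & den > 0
    out[inside] <- num[inside] / den[inside]
  }
  intensity_volume(out, volume$spacing, volume$affine)
}

#' Normalize region intensities by the non-zero voxel mean
#'
#' Extracts the intensities at region voxels and divides them by the mean of
#' the strictly positive values among them, so the normalized non-zero
#' voxels average exactly 1. These dimensionless samples are the input to
#' the Gaussian mixture fit.
#'
#' @param volume An [intensity_volume()] (typically already smoothed).
#' @param region A [binary_mask()] on the same grid.
#' @param side Optional hemisphere tag carried along for provenance.
#' @return An object of class `region_samples`: list with `values`
#'   (normalized intensities), `voxel_index` (n x 3 integer matrix of grid
#'   coordinates), `norm_constant` (the non-zero mean, scanner units) and
#'   `side`.
#' @export
normalize_region <- function(volume, region, side = NULL) {
  stopifnot(inherits(volume, "intensity_volume"),
            inherits(region, "binary_mask"))
  assert_same_grid(volume, region)
  idx <- which(region$data, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("degenerate prior region: no voxels in region")
  vals <- volume$data[region$data]
  nz <- vals > 0
  if (!any(nz))
    stop("degenerate prior region: all region intensities are zero")
  m <- mean(vals[nz])
  structure(
    list(values = vals / m, voxel_index = idx, norm_constant = m,
         side = side),
    class = "region_samples"
  )
}

#' @export
print.region_samples <- function(x, ...) {
  cat("<region_samples> ", length(x$values), " voxels",
      if (!is.null(x$side)) paste0(" (", x$side, " hemisphere)"),
      ", normalized by non-zero mean ", signif(x$norm_constant, 5),
      "\n  range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}
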