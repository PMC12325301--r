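# Grid comparison tolerance (mm). Coregistered volumes share headers up to
# float noise, so anything beyond this is a genuine misalignment.
.grid_tol <- 1e-4

#' Construct an intensity volume
#'
#' A lightweight container for a 3-D scalar image: the voxel array, the voxel
#' spacing in mm, and the affine (voxel-to-world) matrix used as a grid
#' identity token.
#'
#' @param data 3-D numeric array of finite intensities.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm
#'   (strictly positive).
#' @param affine Optional 4x4 voxel-to-world matrix; `NULL` means an
#'   axis-aligned grid implied by `spacing`.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("intensity volume must be a 3-D array, got ", length(dim(data)),
         " dimensions")
  if (!all(is.finite(data)))
    stop("intensity volume contains non-finite voxels (NaN or Inf)")
  structure(
    list(data = data, spacing = .check_spacing(spacing),
         affine = .default_affine(affine, spacing)),
    class = "intensity_volume"
  )
}

#' Construct a label volume
#'
#' An integer-valued parcellation (FreeSurfer aseg convention) aligned to an
#' intensity volume.
#'
#' @inheritParams intensity_volume
#' @param data 3-D array of non-negative integers.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("label volume must be a 3-D array")
  if (!all(is.finite(data)))
    stop("label volume contains non-finite voxels")
  if (any(data < 0) || any(data != round(data)))
    stop("label volume must contain non-negative integers")
  storage.mode(data) <- "integer"
  structure(
    list(data = data, spacing = .check_spacing(spacing),
         affine = .default_affine(affine, spacing)),
    class = "label_volume"
  )
}

#' Construct a binary mask
#'
#' @param data 3-D logical (or coercible 0/1) array.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("binary mask must be a 3-D array")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1)))
      stop("binary mask data must be logical or contain only 0/1")
    data <- array(data > 0, dim = dim(data))
  }
  structure(
    list(data = data, spacing = .check_spacing(spacing),
         affine = .default_affine(affine, spacing)),
    class = "binary_mask"
  )
}

.check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values (mm)")
  spacing
}

.default_affine <- function(affine, spacing) {
  if (is.null(affine)) return(diag(c(as.numeric(spacing), 1)))
  affine <- unclass(affine)
  attributes(affine) <- list(dim = dim(affine))
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 matrix")
  affine
}

#' Read a NIfTI volume from disk
#'
#' Loads a `.nii` / `.nii.gz` file as either an intensity or a label volume.
#' Intensity volumes are checked for non-finite voxels; label volumes are
#' rounded-checked and stored as integers.
#'
#' @param path Path to a NIfTI-1 file.
#' @param kind Either `"intensity"` or `"label"`.
#' @return An [intensity_volume()] or [label_volume()].
#' @export
read_volume <- function(path, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path, internal = FALSE),
                  error = function(e)
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e)))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  nd <- length(dim(arr))
  if (nd == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim = dim(arr)[1:3])
  } else if (nd != 3L) {
    stop("expected a 3-D volume, got ", nd, " dimensions in ", path)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- unname(unclass(RNifti::xform(img)))
  if (kind == "intensity") {
    intensity_volume(arr, spacing, affine)
  } else {
    label_volume(arr, spacing, affine)
  }
}

#' Write a binary mask as a NIfTI file
#'
#' The mask is stored as unsigned 8-bit integers with values 0/1; the header
#' spacing is taken from the mask.
#'
#' @param mask A [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- array(as.integer(mask$data), dim = dim(mask$data))
  pd <- c(-1, mask$spacing, 0, 0, 0, 0)
  img <- RNifti::asNifti(arr, reference = list(pixdim = pd),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' Companion to [write_mask()]: any strictly positive voxel becomes `TRUE`.
#'
#' @param path Path to a NIfTI file.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  lab <- read_volume(path, kind = "label")
  binary_mask(lab$data > 0L, lab$spacing, lab$affine)
}

#' Physical volume of a mask in millilitres
#'
#' Voxel count times the voxel volume (product of spacings, mm^3), converted
#' to ml (1 ml = 1000 mm^3).
#'
#' @param mask A [binary_mask()].
#' @return Volume in ml (0 for an empty mask).
#' @export
volume_ml <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Assert that two volumes share a voxel grid
#'
#' Shapes must match exactly; spacings and affine entries within an absolute
#' tolerance of 1e-4 mm. The segmentation pipeline refuses misaligned inputs
#' rather than resampling.
#'
#' @param a,b Volumes or masks (any of the three container classes).
#' @return Invisibly `TRUE`; stops with a descriptive error on mismatch.
#' @export
assert_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: shapes (", paste(dim(a$data), collapse = ","),
         ") vs (", paste(dim(b$data), collapse = ","), ")")
  if (any(abs(a$spacing - b$spacing) > .grid_tol))
    stop("grid mismatch: spacings (", paste(a$spacing, collapse = ","),
         ") vs (", paste(b$spacing, collapse = ","), ") differ beyond ",
         .grid_tol, " mm")
  if (!is.null(a$affine) && !is.null(b$affine) &&
      any(abs(a$affine - b$affine) > .grid_tol))
    stop("grid mismatch: affine matrices differ beyond ", .grid_tol)
  invisible(TRUE)
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("<intensity_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  intensity range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(as.vector(x$data)))
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  labels: ", paste(utils::head(labs, 12), collapse = " "),
      if (length(labs) > 12) " ...", "\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  ", sum(x$data), " foreground voxels (",
      signif(volume_ml(x), 5), " ml)\n", sep = "")
  invisible(x)
}
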