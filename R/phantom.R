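# Synthetic FLAIR-like phantoms with known choroid-plexus ground truth.
#
# Anatomy per hemisphere: an ellipsoidal ventricle lumen of suppressed
# (dark) fluid; a partial-volume ramp across the ventricle wall, rising
# linearly from fluid to bright periventricular tissue; and bright plexus
# blobs attached to the wall from inside, with their own thin
# partial-volume edge. The emitted label map mimics a FreeSurfer aseg: the
# ventricle label traces the anatomical lumen (optionally dilated, i.e.
# imperfect), and the plexus label is a deliberately coarse dilated
# superset of the true blobs clipped to the lumen. Because the true plexus
# touches the boundary of the labelled region, the pipeline's one-voxel
# erosion removes a small contact patch of true plexus — reproducing the
# slight, systematic volume underestimation the method shows on real data.

#' Phantom specification
#'
#' All geometric quantities are in voxels; intensities are in arbitrary
#' scanner units. With the default intensities the region-normalized class
#' means fall in the neighbourhood of the empirical mixture initialization
#' of [gmm_init_default()] (dark fluid well below 1, wall partial volume
#' near 1, plexus a few times the region mean).
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param spacing_mm Voxel spacing in mm.
#' @param sides Character vector: which hemispheres to build.
#' @param ventricle_center Named list (left/right) of lumen centres
#'   in voxels.
#' @param ventricle_semiaxes Ellipsoid semi-axes of the ventricle lumen.
#' @param shell_width_voxels Full width of the partial-volume wall ramp.
#' @param n_blobs Plexus blobs per hemisphere.
#' @param blob_radius_range Min/max blob radius in voxels.
#' @param blob_jitter_sd Positional jitter (voxels, sd) on blob centres.
#' @param blob_edge_voxels Width of the partial-volume edge of each blob.
#' @param wall_poke_voxels How far blobs extend past the lumen surface
#'   into the wall (they are clipped to the lumen; this controls the size
#'   of the wall-contact patch that prior erosion removes).
#' @param intensity_means Named vector with entries `csf`, `wall`, `cp`,
#'   `background` (scanner units); must satisfy csf < wall and csf < cp.
#' @param intensity_sds Named per-class noise sds (the wall sd applies at
#'   the tissue end of the ramp and the plexus sd at full blob coverage;
#'   both taper with the local mixing fraction).
#' @param noise_sd Global additive scanner noise sd.
#' @param noise_model `"gaussian"` (matching the mixture assumptions) or
#'   `"rician"` for robustness experiments.
#' @param prior_dilation_voxels How far the emitted ventricle label
#'   over-covers the anatomical lumen (0 = trace it exactly).
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing_mm = c(1, 1, 1),
                         sides = c("left", "right"),
                         ventricle_center = list(left = c(20, 32, 32),
                                                 right = c(45, 32, 32)),
                         ventricle_semiaxes = c(8, 13, 10),
                         shell_width_voxels = 2.4,
                         n_blobs = 5L,
                         blob_radius_range = c(2, 3),
                         blob_jitter_sd = 0.5,
                         blob_edge_voxels = 0.3,
                         wall_poke_voxels = 0.3,
                         intensity_means = c(csf = 10, wall = 520,
                                             cp = 360, background = 120),
                         intensity_sds = c(csf = 3, wall = 15,
                                           cp = 25, background = 10),
                         noise_sd = 8,
                         noise_model = c("gaussian", "rician"),
                         prior_dilation_voxels = 0L,
                         seed = 101L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            all(spacing_mm > 0), all(sides %in% c("left", "right")),
            length(sides) >= 1L,
            shell_width_voxels > 0, n_blobs >= 0L,
            length(blob_radius_range) == 2L,
            all(blob_radius_range > 0),
            blob_radius_range[1] <= blob_radius_range[2],
            blob_edge_voxels > 0, wall_poke_voxels >= 0,
            noise_sd >= 0, prior_dilation_voxels >= 0L)
  if (!(intensity_means["csf"] < intensity_means["wall"] &&
        intensity_means["csf"] < intensity_means["cp"]))
    stop("intensity ordering must be csf < wall and csf < cp")
  structure(
    list(grid_shape = as.integer(grid_shape),
         spacing_mm = as.numeric(spacing_mm), sides = sides,
         ventricle_center = ventricle_center,
         ventricle_semiaxes = ventricle_semiaxes,
         shell_width_voxels = shell_width_voxels,
         n_blobs = as.integer(n_blobs),
         blob_radius_range = blob_radius_range,
         blob_jitter_sd = blob_jitter_sd,
         blob_edge_voxels = blob_edge_voxels,
         wall_poke_voxels = wall_poke_voxels,
         intensity_means = intensity_means,
         intensity_sds = intensity_sds, noise_sd = noise_sd,
         noise_model = noise_model,
         prior_dilation_voxels = as.integer(prior_dilation_voxels),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Named phantom presets
#'
#' Fixed, documented phantom regimes: `"default"` (low noise, medium
#' plexus volume), `"noisy"` (triple the scanner noise), `"small_cp"`
#' (fewer, smaller blobs — the low-volume regime that is hardest for
#' intensity clustering), `"one_sided"` (right hemisphere absent from both
#' anatomy and labels).
#'
#' @param name Preset name.
#' @param seed Optional seed override.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("default", "noisy", "small_cp",
                                    "one_sided"),
                           seed = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    default = phantom_spec(seed = 101L),
    noisy = phantom_spec(noise_sd = 24, seed = 202L),
    small_cp = phantom_spec(n_blobs = 4L, blob_radius_range = c(1.8, 2.4),
                            seed = 303L),
    one_sided = phantom_spec(sides = "left", seed = 404L)
  )
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  spec
}

# Evaluate with the spec's seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Normalized ellipsoid coordinate (1 on the surface) for every voxel.
.ellipsoid_dist2 <- function(dims, center, semiaxes) {
  x <- ((seq_len(dims[1]) - center[1]) / semiaxes[1])^2
  y <- ((seq_len(dims[2]) - center[2]) / semiaxes[2])^2
  z <- ((seq_len(dims[3]) - center[3]) / semiaxes[3])^2
  outer(outer(x, y, "+"), z, "+")
}

#' Generate a phantom
#'
#' Builds the intensity volume, the imperfect FreeSurfer-style label
#' volume (ventricle labels 4/43, plexus labels 31/63), and the exact
#' ground-truth plexus mask (voxels with blob coverage of at least one
#' half, clipped to the lumen). Global additive noise is applied and
#' intensities are clipped at zero. Fully deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `flair` ([intensity_volume()]), `labels`
#'   ([label_volume()]), `truth_cp` ([binary_mask()]), and `spec`.
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, .phantom_build(spec))
}

.phantom_build <- function(spec) {
  dims <- spec$grid_shape
  nvox <- prod(dims)
  mu <- spec$intensity_means; sdv <- spec$intensity_sds
  intensity <- array(stats::rnorm(nvox, mu["background"],
                                  sdv["background"]), dim = dims)
  labels <- array(0L, dim = dims)
  truth <- array(FALSE, dim = dims)
  lab_ids <- list(left = c(lv = 4L, cp = 31L), right = c(lv = 43L, cp = 63L))
  elem <- structuring_element(1L)
  cs <- lapply(1:3, function(a) seq_len(dims[a]))
  # half-width of the wall ramp in normalized ellipsoid coordinate
  rho_h <- spec$shell_width_voxels / (2 * min(spec$ventricle_semiaxes))

  for (side in spec$sides) {
    ctr <- spec$ventricle_center[[side]]
    ax <- spec$ventricle_semiaxes
    rho <- sqrt(.ellipsoid_dist2(dims, ctr, ax))
    lumen <- rho <= 1
    if (!any(lumen))
      stop("ventricle lumen misses the grid (", side, " hemisphere)")
    # wall partial-volume ramp: fluid -> tissue across [1 - rho_h, 1 + rho_h]
    t <- pmin(pmax((rho - (1 - rho_h)) / (2 * rho_h), 0), 1)
    zone <- rho <= 1 + rho_h + 0.15
    base <- mu["csf"] + t * (mu["wall"] - mu["csf"])
    class_sd <- sdv["csf"] + t * (sdv["wall"] - sdv["csf"])
    intensity[zone] <- base[zone] +
      stats::rnorm(sum(zone), 0, class_sd[zone])

    # plexus blobs: spheres tangent to the wall from inside, with a thin
    # partial-volume edge; coverage fraction in [0, 1]
    frac <- array(0, dim = dims)
    for (b in seq_len(spec$n_blobs)) {
      rad <- stats::runif(1, spec$blob_radius_range[1],
                          spec$blob_radius_range[2])
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      f <- 1 - (rad - spec$wall_poke_voxels) / min(ax)
      p <- ctr + f * u * ax + stats::rnorm(3, 0, spec$blob_jitter_sd)
      if (any(p - rad < 1) || any(p + rad > dims))
        stop("plexus blob would exit the grid")
      dist <- sqrt(outer(outer((cs[[1]] - p[1])^2, (cs[[2]] - p[2])^2, "+"),
                         (cs[[3]] - p[3])^2, "+"))
      fb <- pmin(pmax(0.5 + (rad - dist) / spec$blob_edge_voxels, 0), 1)
      frac <- pmax(frac, fb)
    }
    frac[!lumen] <- 0
    pv <- frac > 0
    if (any(pv))
      intensity[pv] <- intensity[pv] +
        frac[pv] * (mu["cp"] - intensity[pv]) +
        stats::rnorm(sum(pv), 0, sdv["cp"] * frac[pv])
    blobs <- frac >= 0.5

    # imperfect prior labels: LV traces (or over-covers) the lumen, CP is
    # a coarse dilated superset of the true blobs clipped to the lumen
    lv_mask <- binary_mask(lumen, spec$spacing_mm)
    for (d in seq_len(spec$prior_dilation_voxels))
      lv_mask <- dilate_mask(lv_mask, elem)
    labels[lv_mask$data] <- lab_ids[[side]]["lv"]
    cp_lab <- dilate_mask(binary_mask(blobs, spec$spacing_mm), elem)
    labels[cp_lab$data & lumen] <- lab_ids[[side]]["cp"]
    truth <- truth | blobs
  }

  if (spec$noise_sd > 0) {
    if (spec$noise_model == "gaussian") {
      intensity <- intensity + stats::rnorm(nvox, 0, spec$noise_sd)
    } else {
      # Rician: magnitude of a complex signal with Gaussian channel noise
      re <- intensity + stats::rnorm(nvox, 0, spec$noise_sd)
      im <- stats::rnorm(nvox, 0, spec$noise_sd)
      intensity <- sqrt(re^2 + im^2)
    }
  }
  intensity[intensity < 0] <- 0

  list(flair = intensity_volume(intensity, spec$spacing_mm),
       labels = label_volume(labels, spec$spacing_mm),
       truth_cp = binary_mask(truth, spec$spacing_mm),
       spec = spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", paste(x$grid_shape, collapse = "x"),
      " grid, spacing ", paste(x$spacing_mm, collapse = "x"),
      " mm, sides: ", paste(x$sides, collapse = "+"), "\n  ", x$n_blobs,
      " plexus blobs/side, radius ",
      paste(x$blob_radius_range, collapse = "-"), " vox, noise sd ",
      x$noise_sd, " (", x$noise_model, "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
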