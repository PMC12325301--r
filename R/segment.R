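# Whole-pipeline orchestration: per hemisphere, build the anatomical prior
# (LV + CP labels), erode by one voxel, smooth, normalize, fit the
# 3-component mixture by EM, hard-assign the brightest component as choroid
# plexus, then union the two hemisphere masks.

#' Default pipeline configuration
#'
#' Nested list of every tunable of the segmentation pipeline with its
#' default. Any subset can be overridden through `...` (e.g.
#' `cpseg_config(smooth = list(sigma_voxels = 1))`); unnamed fields keep
#' their defaults.
#'
#' @param ... Named overrides merged (recursively) into the defaults.
#' @return Configuration list with entries `labels`, `erosion`, `smooth`,
#'   `gmm`.
#' @export
cpseg_config <- function(...) {
  cfg <- list(
    labels = list(left = list(lv = 4L, cp = 31L),
                  right = list(lv = 43L, cp = 63L)),
    erosion = list(radius_voxels = 1L, shape = "sphere"),
    smooth = list(sigma_voxels = 0.5, masked = TRUE),
    gmm = list(means = c(0.15, 1.5, 4),
               sds = c(0.02, 0.1, 1.5),
               weights = c(0.45, 0.5, 0.05),
               tol = 1e-6, max_iter = 500L, sd_floor = 1e-4)
  )
  .merge_config(cfg, list(...))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may define any subset of the keys of [cpseg_config()]; missing
#' keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  .merge_config(cpseg_config(), yaml::read_yaml(path))
}

#' Segment the choroid plexus with a region-informed Gaussian mixture
#'
#' Runs the full one-stage pipeline on a T2-FLAIR volume and a
#' FreeSurfer-style parcellation sharing its voxel grid. For each
#' hemisphere: the lateral-ventricle and choroid-plexus labels are merged
#' into a prior region, eroded by one voxel with a spherical kernel,
#' the FLAIR intensities are Gaussian-smoothed within the eroded region and
#' normalized by their non-zero mean, a 3-component Gaussian mixture is
#' fitted by EM from the empirical initialization, and voxels whose maximum
#' posterior belongs to the brightest fitted component are labelled choroid
#' plexus. Hemisphere masks are unioned into the bilateral output. The
#' whole procedure is deterministic: identical inputs give bit-identical
#' results.
#'
#' @param flair An [intensity_volume()] (bias-corrected, coregistered
#'   T2-FLAIR).
#' @param labels A [label_volume()] on the same grid.
#' @param config Configuration from [cpseg_config()].
#' @return An object of class `cp_seg` with fields `cp_mask` (bilateral
#'   [binary_mask()]), `per_side` (per-hemisphere mask, fit, region voxel
#'   counts, volume), `volume_ml` (named left/right/bilateral), `config`
#'   and `version`.
#' @export
cp_segment <- function(flair, labels, config = cpseg_config()) {
  stopifnot(inherits(flair, "intensity_volume"),
            inherits(labels, "label_volume"))
  assert_same_grid(flair, labels)
  elem <- structuring_element(config$erosion$radius_voxels,
                              config$erosion$shape)
  init <- mixture_params(config$gmm$means, config$gmm$sds,
                         config$gmm$weights)
  per_side <- list()
  for (side in c("left", "right")) {
    hemi <- hemisphere_labels(side,
                              lv = config$labels[[side]]$lv,
                              cp = config$labels[[side]]$cp)
    per_side[[side]] <- .segment_side(flair, labels, hemi, elem, init,
                                      config)
  }
  if (is.null(per_side$left) && is.null(per_side$right))
    stop("both hemispheric prior regions are empty; check the label volume")
  empty <- binary_mask(array(FALSE, dim(flair$data)), flair$spacing,
                       flair$affine)
  lmask <- if (is.null(per_side$left)) empty else per_side$left$cp_mask
  rmask <- if (is.null(per_side$right)) empty else per_side$right$cp_mask
  bilateral <- binary_mask(lmask$data | rmask$data, flair$spacing,
                           flair$affine)
  vols <- c(left = volume_ml(lmask), right = volume_ml(rmask))
  structure(
    list(cp_mask = bilateral, per_side = per_side,
         volume_ml = c(vols, bilateral = sum(vols)),
         config = config,
         version = as.character(utils::packageVersion("cpseg"))),
    class = "cp_seg"
  )
}

# One hemisphere: returns NULL (with a warning) when the prior region or
# its erosion is empty, so the other side can still be segmented.
.segment_side <- function(flair, labels, hemi, elem, init, config) {
  region <- withCallingHandlers(
    merge_region(labels, hemi),
    warning = function(w) invokeRestart("muffleWarning"))
  n_region <- sum(region$data)
  if (n_region == 0L) {
    warning("no prior region for ", hemi$side, " hemisphere; side skipped")
    return(NULL)
  }
  eroded <- erode_mask(region, elem)
  n_eroded <- sum(eroded$data)
  if (n_eroded == 0L) {
    warning("prior region of ", hemi$side,
            " hemisphere vanished under erosion; side skipped")
    return(NULL)
  }
  smoothed <- if (config$smooth$sigma_voxels > 0) {
    smooth_volume(flair, config$smooth$sigma_voxels,
                  domain = if (isTRUE(config$smooth$masked)) eroded)
  } else flair
  samples <- normalize_region(smoothed, eroded, side = hemi$side)
  fit <- gmm_fit(samples, init = init, tol = config$gmm$tol,
                 max_iter = config$gmm$max_iter,
                 sd_floor = config$gmm$sd_floor)
  is_cp <- assign_cp(samples, fit)
  mask_arr <- array(FALSE, dim(flair$data))
  mask_arr[samples$voxel_index[is_cp, , drop = FALSE]] <- TRUE
  cp_mask <- binary_mask(mask_arr, flair$spacing, flair$affine)
  list(side = hemi$side, cp_mask = cp_mask, fit = fit,
       region_voxels = n_region, eroded_voxels = n_eroded,
       eroded_region = eroded, volume_ml = volume_ml(cp_mask))
}

#' @export
print.cp_seg <- function(x, ...) {
  cat("Region-informed GMM choroid-plexus segmentation\n")
  for (side in c("left", "right")) {
    s <- x$per_side[[side]]
    if (is.null(s)) {
      cat(sprintf("  %-5s hemisphere: empty prior region (skipped)\n", side))
    } else {
      cat(sprintf(
        "  %-5s hemisphere: prior %d voxels (eroded %d), CP %.4f ml%s\n",
        side, s$region_voxels, s$eroded_voxels, s$volume_ml,
        if (!s$fit$converged) " [EM not converged]" else ""))
    }
  }
  cat(sprintf("  bilateral CP volume: %.4f ml (%d voxels)\n",
              x$volume_ml[["bilateral"]], sum(x$cp_mask$data)))
  invisible(x)
}

#' @export
summary.cp_seg <- function(object, ...) {
  cat("Choroid-plexus segmentation summary\n\n")
  print(object)
  for (side in c("left", "right")) {
    s <- object$per_side[[side]]
    if (is.null(s)) next
    cat("\nFitted mixture,", side, "hemisphere (normalized intensity):\n")
    print(coef(s$fit))
    cat(sprintf("  EM: %d iterations, final log-likelihood %.4f\n",
                s$fit$n_iter, s$fit$loglik_trace[s$fit$n_iter]))
  }
  invisible(object)
}

#' @export
coef.cp_seg <- function(object, ...) {
  lapply(Filter(Negate(is.null), object$per_side), function(s) coef(s$fit))
}

#' Report volumes and (optionally) accuracy metrics for a segmentation
#'
#' Without ground truth, the report carries the per-side and bilateral
#' volumes plus the fitted mixture parameters. With a ground-truth mask on
#' the same grid it additionally contains the full [metrics_report()]
#' (DSC, HD95, VD%).
#'
#' @param result A `cp_seg` object from [cp_segment()].
#' @param truth Optional ground-truth [binary_mask()].
#' @return A list (class `cp_report`) serializable to JSON with
#'   [write_report()].
#' @export
cp_report <- function(result, truth = NULL) {
  stopifnot(inherits(result, "cp_seg"))
  rep <- list(
    volumes_ml = as.list(result$volume_ml),
    mixture = lapply(Filter(Negate(is.null), result$per_side), function(s)
      list(means = s$fit$params$means, sds = s$fit$params$sds,
           weights = s$fit$params$weights, converged = s$fit$converged,
           n_iter = s$fit$n_iter)),
    region_voxels = lapply(Filter(Negate(is.null), result$per_side),
                           function(s) c(prior = s$region_voxels,
                                         eroded = s$eroded_voxels)),
    config = result$config,
    version = result$version
  )
  if (!is.null(truth)) {
    assert_same_grid(result$cp_mask, truth)
    m <- metrics_report(result$cp_mask, truth)
    rep$metrics <- list(dsc = m$dsc, hd95_mm = m$hd95_mm,
                        vd_pct_signed = m$vd_pct_signed,
                        vd_pct_abs = m$vd_pct_abs,
                        vol_pred_ml = m$vol_pred_ml,
                        vol_true_ml = m$vol_true_ml)
  }
  class(rep) <- "cp_report"
  rep
}

#' Write a report as JSON
#'
#' @param report A `cp_report` or `cp_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
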