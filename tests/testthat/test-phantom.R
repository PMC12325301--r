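test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- phantom_preset("default")
  p1 <- phantom_generate(spec)
  p2 <- phantom_generate(spec)
  expect_identical(p1$flair$data, p2$flair$data)
  expect_identical(p1$labels$data, p2$labels$data)
  expect_identical(p1$truth_cp$data, p2$truth_cp$data)
  p3 <- phantom_generate(phantom_preset("default", seed = 999))
  expect_false(identical(p1$flair$data, p3$flair$data))
  # generation does not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(phantom_generate(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("phantom structure follows its specification", {
  # zero blobs -> empty truth
  p0 <- phantom_generate(phantom_spec(n_blobs = 0L, seed = 1))
  expect_equal(sum(p0$truth_cp$data), 0)
  # one-sided preset has no right-hemisphere labels
  p1 <- phantom_generate(phantom_preset("one_sided"))
  expect_false(any(p1$labels$data %in% c(43L, 63L)))
  expect_true(any(p1$labels$data == 4L))
  # small_cp plants less plexus than default
  expect_lt(volume_ml(phantom_generate(phantom_preset("small_cp"))$truth_cp),
            volume_ml(phantom_generate(phantom_preset("default"))$truth_cp))
  # the prior labels cover the truth
  pd <- phantom_generate(phantom_preset("default"))
  covered <- pd$labels$data[pd$truth_cp$data]
  expect_true(all(covered %in% c(4L, 31L, 43L, 63L)))
  # also when the ventricle label over-covers the lumen
  pdil <- phantom_generate(phantom_spec(prior_dilation_voxels = 2L,
                                        seed = 7))
  expect_true(all(pdil$labels$data[pdil$truth_cp$data] > 0L))
  expect_gt(sum(pdil$labels$data > 0), sum(pd$labels$data > 0))
})

test_that("planted class ordering survives region normalization", {
  ph <- phantom_generate(phantom_preset("default"))
  hemi <- hemisphere_labels("left")
  region <- erode_mask(merge_region(ph$labels, hemi))
  s <- normalize_region(smooth_volume(ph$flair, 0.5, region), region)
  truth <- ph$truth_cp$data[region$data]
  # empirical class means: plexus > wall partial volume > fluid
  rho <- sqrt(cpseg:::.ellipsoid_dist2(dim(ph$flair$data), c(20, 32, 32),
                                       c(8, 13, 10)))[region$data]
  fluid <- !truth & rho <= 0.8
  wallpv <- !truth & rho > 0.8
  expect_gt(mean(s$values[truth]), mean(s$values[wallpv]))
  expect_gt(mean(s$values[wallpv]), mean(s$values[fluid]))
  # fluid is dark relative to the region mean, plexus several times it
  expect_lt(mean(s$values[fluid]), 0.6)
  expect_gt(mean(s$values[truth]), 2.5)
})

test_that("EM recovers the planted class structure from a phantom", {
  ph <- phantom_generate(phantom_preset("default"))
  hemi <- hemisphere_labels("left")
  region <- erode_mask(merge_region(ph$labels, hemi))
  s <- normalize_region(smooth_volume(ph$flair, 0.5, region), region)
  fit <- gmm_fit(s)
  truth <- ph$truth_cp$data[region$data]
  # the brightest fitted component sits near the empirical plexus mean
  cp_mean <- mean(s$values[truth])
  expect_lt(abs(max(fit$params$means) - cp_mean) / cp_mean, 0.15)
  # and its weight is near the plexus voxel fraction
  expect_equal(fit$params$weights[cp_component(fit$params)],
               mean(truth), tolerance = 0.05)
})

test_that("phantom rejects inconsistent specifications", {
  expect_error(phantom_spec(intensity_means = c(csf = 500, wall = 300,
                                                cp = 400,
                                                background = 100)),
               "ordering")
  expect_error(phantom_spec(blob_radius_range = c(3, 2)))
  expect_error(
    phantom_generate(phantom_spec(ventricle_center = list(
      left = c(4, 32, 32), right = c(45, 32, 32)),
      blob_radius_range = c(5, 6), seed = 2)),
    "exit the grid")
  # rician noise is available and changes the realization
  pg <- phantom_generate(phantom_spec(seed = 3))
  pr <- phantom_generate(phantom_spec(seed = 3, noise_model = "rician"))
  expect_false(identical(pg$flair$data, pr$flair$data))
})
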