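test_that("the radius-1 sphere is the 6-connected cross", {
  e <- structuring_element(1L)
  expect_equal(nrow(e), 7L)
  expect_true(all(rowSums(e^2) <= 1))
  # radius-2 ball has 33 offsets (i^2+j^2+k^2 <= 4)
  expect_equal(nrow(structuring_element(2L)), 33L)
  # box at radius 1 is the full 26-neighbourhood plus centre
  expect_equal(nrow(structuring_element(1L, "box")), 27L)
  expect_error(structuring_element(0L), "radius")
})

test_that("erosion matches hand-derived solid-shape results", {
  # solid 5^3 cube inside an 9^3 grid erodes to its 3^3 interior
  arr <- array(FALSE, dim = c(9, 9, 9)); arr[3:7, 3:7, 3:7] <- TRUE
  er <- erode_mask(binary_mask(arr))
  expect_equal(sum(er$data), 27)
  expect_true(all(which(er$data, arr.ind = TRUE) >= 4) &&
                all(which(er$data, arr.ind = TRUE) <= 6))
  # single voxel vanishes
  one <- array(FALSE, dim = c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(sum(erode_mask(binary_mask(one))$data), 0)
  # full-grid mask: out-of-grid is background, so only the 2^3 interior
  # of a 4^3 grid survives
  full <- binary_mask(array(TRUE, dim = c(4, 4, 4)))
  expect_equal(sum(erode_mask(full)$data), 8)
})

test_that("erosion equals the brute-force oracle on random masks", {
  set.seed(73)
  elems <- list(structuring_element(1L), structuring_element(1L, "box"))
  for (i in 1:20) {
    m <- random_blob_mask(c(10, 10, 10))
    for (e in elems)
      expect_identical(erode_mask(m, e)$data, brute_erode(m, e)$data)
  }
})

test_that("erosion is anti-extensive and monotone", {
  set.seed(74)
  for (i in 1:10) {
    m1 <- random_blob_mask(c(10, 10, 10))
    m2 <- binary_mask(m1$data | random_blob_mask(c(10, 10, 10))$data)
    e1 <- erode_mask(m1); e2 <- erode_mask(m2)
    expect_true(all(m1$data[e1$data]))          # erode(m) subset of m
    expect_true(all(e2$data[e1$data]))          # monotone in the mask
    # dilation is extensive and inverse-monotone partner
    expect_true(all(dilate_mask(m1)$data[m1$data]))
  }
})

test_that("merge_region selects exactly the hemisphere's labels", {
  lab <- array(0L, dim = c(6, 6, 6))
  lab[1:5, 1, 1] <- 4L          # 5 left-LV voxels
  lab[1:5, 2, 1] <- 4L          # 10 total
  lab[1:3, 3, 1] <- 31L         # 3 left-CP voxels
  labels <- label_volume(lab)
  m <- merge_region(labels, hemisphere_labels("left"))
  expect_equal(sum(m$data), 13)
  expect_warning(merge_region(labels, hemisphere_labels("right")), "empty")
  expect_equal(
    sum(suppressWarnings(merge_region(labels,
                                      hemisphere_labels("right")))$data), 0)
  # custom label IDs override the FreeSurfer defaults
  m2 <- merge_region(labels, hemisphere_labels("right", lv = 4L, cp = 31L))
  expect_equal(sum(m2$data), 13)
  expect_error(hemisphere_labels("left", lv = 5, cp = 5), "distinct")
})

test_that("boundary extraction matches the brute-force neighbour check", {
  # solid 3^3 cube: all 26 shell voxels are boundary, the centre is not
  arr <- array(FALSE, dim = c(7, 7, 7)); arr[3:5, 3:5, 3:5] <- TRUE
  b <- boundary_voxels(binary_mask(arr))
  expect_equal(nrow(b), 26)
  one <- array(FALSE, dim = c(5, 5, 5)); one[2, 3, 4] <- TRUE
  expect_equal(unname(boundary_voxels(binary_mask(one))[1, ]), c(2, 3, 4))
  expect_equal(nrow(boundary_voxels(binary_mask(array(FALSE, c(4, 4, 4))))),
               0)
  set.seed(75)
  for (i in 1:10) {
    m <- random_blob_mask(c(10, 10, 10))
    got <- boundary_voxels(m)
    want <- brute_boundary(m)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})
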