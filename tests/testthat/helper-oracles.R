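# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (no erode_mask / boundary_voxels /
# hd95 internals) so equivalence tests are genuine cross-checks.

# Random blobby mask: union of a few random balls on a small grid.
random_blob_mask <- function(dims, n_blobs = 3L, r_range = c(1, 3),
                             spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dim = dims)
  for (b in seq_len(n_blobs)) {
    ctr <- sapply(dims, function(d) runif(1, 1, d))
    rad <- runif(1, r_range[1], r_range[2])
    d2 <- outer(outer((seq_len(dims[1]) - ctr[1])^2,
                      (seq_len(dims[2]) - ctr[2])^2, "+"),
                (seq_len(dims[3]) - ctr[3])^2, "+")
    arr <- arr | (d2 <= rad^2)
  }
  binary_mask(arr, spacing)
}

# Brute-force erosion: loop over every voxel, test every element offset.
brute_erode <- function(mask, elem) {
  d <- dim(mask$data)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask$data[i, j, k]) next
    ok <- TRUE
    for (r in seq_len(nrow(elem))) {
      ii <- i + elem[r, 1]; jj <- j + elem[r, 2]; kk <- k + elem[r, 3]
      if (ii < 1 || jj < 1 || kk < 1 ||
          ii > d[1] || jj > d[2] || kk > d[3] ||
          !mask$data[ii, jj, kk]) { ok <- FALSE; break }
    }
    out[i, j, k] <- ok
  }
  binary_mask(out, mask$spacing)
}

# Brute-force boundary: foreground voxels with a background face neighbour.
brute_boundary <- function(mask) {
  d <- dim(mask$data)
  fg <- which(mask$data, arr.ind = TRUE)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  keep <- logical(nrow(fg))
  for (r in seq_len(nrow(fg))) {
    for (s in 1:6) {
      v <- fg[r, ] + nb[s, ]
      if (any(v < 1) || any(v > d) || !mask$data[v[1], v[2], v[3]]) {
        keep[r] <- TRUE; break
      }
    }
  }
  fg[keep, , drop = FALSE]
}

# Brute-force symmetric percentile Hausdorff via all-pairs distances.
brute_hd <- function(pred, truth, probs = 0.95) {
  a <- sweep(brute_boundary(pred), 2, pred$spacing, "*")
  b <- sweep(brute_boundary(truth), 2, truth$spacing, "*")
  dmat <- sqrt(outer(rowSums(a^2), rowSums(b^2), "+") -
                 2 * (a %*% t(b)))
  dmat[dmat < 0 | is.na(dmat)] <- 0
  max(quantile(apply(dmat, 1, min), probs, names = FALSE),
      quantile(apply(dmat, 2, min), probs, names = FALSE))
}

# Brute-force Dice from explicit TP/FP/FN counts.
brute_dice <- function(pred, truth) {
  tp <- sum(pred$data & truth$data)
  fp <- sum(pred$data & !truth$data)
  fn <- sum(!pred$data & truth$data)
  if (tp + fp + fn == 0) return(1.0)
  2 * tp / (2 * tp + fp + fn)
}

# Direct (non-separable) masked Gaussian convolution at one voxel.
brute_masked_gauss_at <- function(vol, domain, sigma, at) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  d <- dim(vol$data)
  num <- 0; den <- 0
  for (di in -h:h) for (dj in -h:h) for (dk in -h:h) {
    v <- at + c(di, dj, dk)
    if (any(v < 1) || any(v > d)) next
    if (!domain$data[v[1], v[2], v[3]]) next
    w <- exp(-(di^2 + dj^2 + dk^2) / (2 * sigma^2))
    num <- num + w * vol$data[v[1], v[2], v[3]]
    den <- den + w
  }
  num / den
}

# Small aligned intensity/label pair on a shared grid.
tiny_volume_pair <- function(dims = c(6, 6, 6), spacing = c(1, 1, 1)) {
  flair <- intensity_volume(array(runif(prod(dims), 1, 10), dim = dims),
                            spacing)
  lab <- array(0L, dim = dims)
  lab[2:4, 2:4, 2:4] <- 4L
  lab[3, 3, 3] <- 31L
  labels <- label_volume(lab, spacing)
  list(flair = flair, labels = labels)
}
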