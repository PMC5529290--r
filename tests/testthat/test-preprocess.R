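# Background estimation, subtraction, normalization.

vs_std <- c(0.18, 0.06, 0.06)

# minimal MaskSet on a 20^3 grid: cell everywhere, cytosol everywhere
# except a TT line and its immediate surroundings
bgMaskSet <- function(dims = c(20L, 20L, 20L)) {
  cell <- array(TRUE, dims)
  bath <- array(FALSE, dims)
  tt <- array(FALSE, dims); tt[10, 10, 4:16] <- TRUE
  ss <- array(FALSE, dims); ss[, 1, ] <- TRUE
  cyto <- cell
  cyto[8:12, 8:12, ] <- FALSE
  cyto[, 1:2, ] <- FALSE
  new("MaskSet", cell = cell, cytosol = cyto, bath = bath,
      membraneSkeleton = tt, ssSkeleton = ss, ttSkeleton = tt,
      voxelSize = vs_std)
}

test_that("constant cytosol intensity interpolates unchanged to TT voxels", {
  ms <- bgMaskSet()
  img <- array(7.5, dim(ms@cell))
  bg <- estimateBackground(volumeImage(img, vs_std), ms)
  expect_equal(bg[ms@ttSkeleton], rep(7.5, sum(ms@ttSkeleton)))
  expect_equal(bg[ms@cytosol], rep(7.5, sum(ms@cytosol)))
})

test_that("nearest-neighbor interpolation matches a brute-force oracle", {
  ms <- bgMaskSet()
  dims <- dim(ms@cell)
  # linear ramp plus a mild second gradient
  img <- array(0, dims)
  for (x in 1:dims[3]) img[, , x] <- x + 0.1 * matrix(rep(1:dims[2],
      each = dims[1]), dims[1])
  bg <- estimateBackground(volumeImage(img, vs_std), ms, medianRadius_vox = 0L)
  cidx <- which(ms@cytosol, arr.ind = TRUE)
  cco <- sweep(cidx - 0.5, 2, vs_std, "*")
  tidx <- which(ms@cell & !ms@cytosol, arr.ind = TRUE)
  for (k in sample(nrow(tidx), 25)) {
    p <- (tidx[k, ] - 0.5) * vs_std
    d <- sqrt(colSums((t(cco) - p)^2))
    best <- min(d)
    # oracle: value at the tie-broken nearest cytosol voxel (lowest z, y, x)
    cand <- cidx[abs(d - best) <= 1e-12, , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
    expect_equal(bg[matrix(tidx[k, ], 1)], img[matrix(cand[1, ], 1)])
  }
})

test_that("equidistant ties break to the lowest z, then y, then x index", {
  dims <- c(7L, 7L, 7L)
  cell <- array(TRUE, dims)
  cyto <- array(FALSE, dims)
  cyto[2, 4, 4] <- TRUE   # distance 2 voxels in z below
  cyto[6, 4, 4] <- TRUE   # distance 2 voxels in z above
  tt <- array(FALSE, dims); tt[4, 4, 4] <- TRUE
  ms <- new("MaskSet", cell = cell, cytosol = cyto, bath = array(FALSE, dims),
            membraneSkeleton = tt, ssSkeleton = array(FALSE, dims),
            ttSkeleton = tt, voxelSize = vs_std)
  img <- array(0, dims); img[2, 4, 4] <- 11; img[6, 4, 4] <- 99
  bg <- estimateBackground(volumeImage(img, vs_std), ms, medianRadius_vox = 0L)
  expect_equal(bg[4, 4, 4], 11)
})

test_that("background subtraction identities", {
  img <- array(runif(4 * 6 * 6), c(4, 6, 6))
  vi <- volumeImage(img, vs_std)
  expect_equal(imgData(subtractBackground(vi, array(0, dim(img)))), img)
  expect_equal(max(abs(imgData(subtractBackground(vi, img)))), 0)
  expect_error(subtractBackground(vi, array(0, c(4, 6, 5))), "differ")
})

test_that("normalization enforces bath = 1 and SS = 1 and is gain invariant", {
  psf <- isoPSF()
  hs <- renderHalfspaceCalibration(psf, gridDim = c(16L, 128L, 32L))
  masks <- buildMaskSet(hs$membrane, hs$volume, psf)
  pair <- preprocessChannels(hs$membrane, hs$volume, masks, psf)
  expect_equal(mean(imgData(pair@volume)[masks@bath]), 1, tolerance = 1e-6)
  expect_equal(mean(imgData(pair@membrane)[masks@ssSkeleton]), 1,
               tolerance = 1e-6)
  # arbitrary channel gains cancel exactly
  mem2 <- volumeImage(imgData(hs$membrane) * 37.3, voxelSize(hs$membrane))
  vol2 <- volumeImage(imgData(hs$volume) * 0.004, voxelSize(hs$volume))
  pair2 <- preprocessChannels(mem2, vol2, masks, psf)
  expect_equal(imgData(pair2@volume), imgData(pair@volume), tolerance = 1e-9)
  expect_equal(imgData(pair2@membrane), imgData(pair@membrane),
               tolerance = 1e-9)
  # empty bath is rejected
  masks2 <- masks
  masks2@bath[] <- FALSE
  expect_error(normalizePair(hs$volume, hs$membrane, masks2, psf), "bath")
})

test_that("half-space calibration yields V:SA = 0.5 at the surface", {
  psf <- isoPSF()
  hs <- renderHalfspaceCalibration(psf, gridDim = c(16L, 128L, 32L))
  masks <- buildMaskSet(hs$membrane, hs$volume, psf)
  pair <- preprocessChannels(hs$membrane, hs$volume, masks, psf)
  ssv <- imgData(pair@volume)[masks@ssSkeleton] /
    imgData(pair@membrane)[masks@ssSkeleton]
  expect_equal(mean(ssv), 0.5, tolerance = 0.02)
})

test_that("gain invariance propagates to recovered diameters", {
  spec <- cylinderSpec(0.25, "x", gridDim = c(32L, 128L, 96L))
  rend <- renderPhantom(spec, rawPSF())
  masks <- buildMaskSet(rend$membrane, rend$volume, rawPSF())
  base <- computeVSA(preprocessChannels(rend$membrane, rend$volume, masks,
                                        rawPSF()), masks@ttSkeleton)
  memG <- volumeImage(imgData(rend$membrane) * 5.1, voxelSize(rend$membrane))
  volG <- volumeImage(imgData(rend$volume) * 0.02, voxelSize(rend$volume))
  gained <- computeVSA(preprocessChannels(memG, volG, masks, rawPSF()),
                       masks@ttSkeleton)
  expect_equal(diameterValues(gained), diameterValues(base), tolerance = 1e-9)
})
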