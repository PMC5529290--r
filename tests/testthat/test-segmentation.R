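# Thresholding, thinning and mask construction.

test_that("Otsu threshold separates two-level and bimodal data", {
  x <- c(rep(10, 600), rep(100, 400))
  thr <- otsuThreshold(x)
  expect_gt(thr, 10); expect_lt(thr, 100)
  # bimodal Gaussian mixture vs a brute-force between-class-variance scan;
  # ties (flat plateau between well-separated modes) resolved to the
  # plateau midpoint on both sides
  set.seed(42)
  y <- c(rnorm(6e4, 20, 5), rnorm(4e4, 200, 5))
  thr2 <- as.numeric(otsuThreshold(y))
  scan <- function(v, nb = 256L) {
    cand <- seq(min(v), max(v), length.out = nb)
    bcv <- vapply(cand, function(t) {
      lo <- v[v < t]; hi <- v[v >= t]
      if (!length(lo) || !length(hi)) return(0)
      length(lo) / length(v) * length(hi) / length(v) *
        (mean(lo) - mean(hi))^2
    }, numeric(1))
    ties <- which(bcv >= max(bcv) * (1 - 1e-9))
    cand[ties[ceiling(length(ties) / 2)]]
  }
  oracle <- scan(y)
  expect_lt(abs(thr2 - oracle), 15)
  expect_gt(thr2, 20); expect_lt(thr2, 200)
  # independent implementation cross-check (EBImage) on an overlapping
  # mixture whose between-class variance has a unique interior maximum
  set.seed(43)
  y2 <- c(rnorm(5e4, 80, 15), rnorm(5e4, 140, 15))
  y2s <- (y2 - min(y2)) / (max(y2) - min(y2))
  eb <- EBImage::otsu(matrix(y2s, ncol = 1), range = c(0, 1)) *
    (max(y2) - min(y2)) + min(y2)
  expect_lt(abs(as.numeric(otsuThreshold(y2)) - eb),
            (max(y2) - min(y2)) / 256 * 3)
  expect_error(otsuThreshold(rep(1, 100)), "constant")
})

test_that("3D thinning reduces a solid tube to its single-voxel centerline", {
  dims <- c(9L, 15L, 60L)
  m <- array(FALSE, dims)
  for (x in 6:55) m[3:5, 6:10, x] <- TRUE   # solid 3x5x50 bar
  sk <- skeletonize3D(m)
  n <- sum(sk)
  expect_gte(n, 48); expect_lte(n, 52)
  # skeleton is 1-voxel wide: all voxels have <= 2 neighbors except branch
  # points (none expected on a straight bar)
  idx <- which(sk, arr.ind = TRUE)
  nb <- TubuleVSA:::cpp_neighbor_count26(sk, dims)
  expect_true(all(nb[idx] <= 2))
  # idempotence
  expect_identical(skeletonize3D(sk), sk)
  # fixed points and the empty mask
  expect_equal(sum(skeletonize3D(array(FALSE, c(4, 4, 4)))), 0)
  single <- array(FALSE, c(4, 4, 4)); single[2, 2, 2] <- TRUE
  expect_identical(skeletonize3D(single), single)
})

test_that("cell and bath masks from the half-space calibration phantom", {
  psf <- isoPSF()
  hs <- renderHalfspaceCalibration(psf, gridDim = c(16L, 128L, 32L))
  cm <- cellMask(hs$volume, psf)
  pos <- hs$spec@surfacePosition
  ys <- (seq_len(128) - 0.5) * 0.06
  # deep cell rows (>= 1 um inside) are fully in the cell mask
  deepCell <- which(ys > pos + 1)
  expect_true(all(cm$cell[, deepCell, ]))
  # bath mask only on the bath side, away from the boundary
  bidx <- which(cm$bath, arr.ind = TRUE)
  expect_true(all(ys[bidx[, 2]] < pos - 1))
  expect_gt(sum(cm$bath), 0)
  # cell and bath never overlap
  expect_false(any(cm$cell & cm$bath))
  # an all-bath (constant) image cannot be segmented
  expect_error(cellMask(volumeImage(array(1, c(8, 8, 8)), c(0.18, 0.06, 0.06)),
                        psf), "constant")
})

test_that("surface skeleton covers the plane and sits on the membrane peak", {
  psf <- isoPSF()
  hs <- renderHalfspaceCalibration(psf, gridDim = c(24L, 128L, 48L))
  cm <- cellMask(hs$volume, psf)
  ss <- surfaceSkeleton(hs$membrane, hs$volume, cm$cell)
  idx <- which(ss, arr.ind = TRUE)
  # plane lies on the voxel-center layer at the surface position
  jplane <- round(hs$spec@surfacePosition / 0.06 + 0.5)
  expect_true(all(idx[, 2] == jplane))
  # covers > 90% of the plane cross-section
  expect_gt(nrow(idx) / (24 * 48), 0.9)
  expect_error(surfaceSkeleton(hs$membrane, hs$volume, NULL), "cell mask")
})

test_that("z-groove troughs are excluded from the surface sarcolemma", {
  psf <- isoPSF()
  spec <- phantomSpec(gridDim = c(24L, 128L, 160L),
                      voxelSize = c(0.18, 0.06, 0.06), surfaceAxis = "y",
                      surfacePosition = (48 + 0.5) * 0.06,
                      grooveAmplitude = 0.25, groovePeriod = 1.8)
  rend <- renderPhantom(spec, psf)
  cm <- cellMask(rend$volume, psf)
  ss <- surfaceSkeleton(rend$membrane, rend$volume, cm$cell)
  idx <- which(ss, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  # trough = deepest quarter of the corrugation (surface height above
  # the mid position); crest/flank voxels are acceptable
  xs <- (idx[, 3] - 0.5) * 0.06
  h <- spec@surfacePosition + 0.25 * sin(2 * pi * xs / 1.8)
  inTrough <- h > spec@surfacePosition + 0.25 * sin(pi / 4)
  expect_lt(mean(inTrough), 0.10)
})

test_that("TT skeleton tracks the true centerline of a phantom tubule", {
  p <- runPhantomPipeline(cylinderSpec(0.25, "x", gridDim = c(32L, 128L, 96L)))
  idx <- which(p$masks@ttSkeleton, arr.ind = TRUE)
  expect_gt(nrow(idx), 50)
  tb <- cylinderSpec(0.25, "x", gridDim = c(32L, 128L, 96L))@tubules[[1]]
  # every skeleton voxel within 2 voxels of the true centerline
  co <- cbind((idx[, 1] - 0.5) * 0.18, (idx[, 2] - 0.5) * 0.06,
              (idx[, 3] - 0.5) * 0.06)
  dz <- abs(co[, 1] - tb$centerline[1, 1])
  dy <- abs(co[, 2] - tb$centerline[1, 2])
  expect_true(all(dz <= 2 * 0.18 + 1e-9))
  expect_true(all(dy <= 2 * 0.06 + 1e-9))
  # covers >= 90% of the tubule length inside the eroded cell
  expect_gt(diff(range(co[, 3])), 0.9 * (diff(range(tb$centerline[, 3])) - 1.2))
  # a tubule-free phantom yields an empty TT skeleton
  hs <- renderHalfspaceCalibration(isoPSF(), gridDim = c(16L, 96L, 24L))
  mhs <- buildMaskSet(hs$membrane, hs$volume, isoPSF())
  expect_equal(sum(mhs@ttSkeleton), 0)
})

test_that("cytosol mask set algebra", {
  dims <- c(8L, 24L, 24L)
  cell <- array(FALSE, dims); cell[, 9:24, ] <- TRUE
  tt <- array(FALSE, dims); tt[4, 16, 6:18] <- TRUE
  vs <- c(0.18, 0.06, 0.06)
  cyto <- cytosolMask(cell, tt, vs, dilation_um = 0.2)
  expect_true(all(cyto[cell == FALSE] == FALSE))     # containment in cell
  # disjoint from the dilated TT neighborhood (one z voxel, three y/x)
  expect_false(any(cyto & tt))
  expect_false(any(cyto[3:5, 13:19, 6:18]))
  # dilating everything empties the cytosol
  expect_error(cytosolMask(cell, cell, vs, dilation_um = 0.2), "empty")
})

test_that("mask set invariants hold on a rendered phantom", {
  p <- runPhantomPipeline(cylinderSpec(0.17, "x", gridDim = c(32L, 128L, 96L)))
  m <- p$masks
  expect_true(validObject(m))
  expect_false(any(m@bath & m@cell))
  expect_true(all(m@cell[m@ttSkeleton]))
  expect_false(any(m@ssSkeleton & m@ttSkeleton))
  # TT skeleton voxels have at most 2 neighbors away from branch points
  nb <- TubuleVSA:::cpp_neighbor_count26(m@ttSkeleton, as.integer(dim(m@cell)))
  expect_true(all(nb[m@ttSkeleton] <= 3))
})
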