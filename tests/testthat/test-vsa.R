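# V:SA <-> diameter calibration, ellipse equivalents, summaries.

test_that("cylindrical calibration reproduces the published species pair", {
  # invert the conversion at the rabbit pair (V:SA 0.139 <-> 0.356 um)
  fwhm <- 0.356 / (2 * 0.139) * sqrt(log(2) / pi)
  expect_equal(fwhm, 0.6015, tolerance = 1e-4)
  # the same FWHM maps the mouse group mean V:SA to 169 nm
  expect_equal(round(vsaToDiameter(0.066, fwhm), 3), 0.169)
  # and the model slope prints as 0.39
  expect_equal(round(modelSlope(fwhm), 2), 0.39)
  # constant computed, not hard-coded
  expect_equal(vsaToDiameter(1, 1) * modelSlope(1), 1, tolerance = 1e-12)
})

test_that("conversion degenerate cases and slope properties", {
  expect_equal(vsaToDiameter(0, 0.6), 0)
  expect_error(vsaToDiameter(0.1, 0), "FWHM")
  expect_error(vsaToDiameter(-0.1, 0.6), "non-negative")
  expect_equal(modelSlope(1.2), modelSlope(0.6) / 2)
  expect_equal(modelSlope(0.6) * 2 * 0.6 / sqrt(log(2) / pi), 1,
               tolerance = 1e-12)
  expect_equal(diameterToVSA(vsaToDiameter(0.1, 0.6), 0.6), 0.1,
               tolerance = 1e-12)
})

test_that("ellipse-equivalent axes match the circle's area/perimeter ratio", {
  # degenerate ellipse
  expect_equal(unname(ellipseEquivalentAxes(1, diameter = 0.356)),
               c(0.356, 0.356))
  ax <- ellipseEquivalentAxes(0.75, diameter = 0.356)
  # elliptic-integral oracle: A/P of the returned ellipse equals D/4
  a <- ax[["major"]] / 2; b <- ax[["minor"]] / 2
  P <- 4 * a * pracma::ellipke(1 - (b / a)^2)$e
  expect_equal(pi * a * b / P, 0.356 / 4, tolerance = 1e-8)
  # independent perimeter oracle by numerical quadrature
  P2 <- integrate(function(th) sqrt((a * sin(th))^2 + (b * cos(th))^2),
                  0, 2 * pi, rel.tol = 1e-10)$value
  expect_equal(P, P2, tolerance = 1e-8)
  expect_equal(b / a, 0.75, tolerance = 1e-12)
  # published approximate axes 0.40/0.32 um agree to ~5%
  expect_equal(unname(ax[["major"]]), 0.40, tolerance = 0.05)
  expect_equal(unname(ax[["minor"]]), 0.32, tolerance = 0.05)
  expect_error(ellipseEquivalentAxes(1.2, diameter = 0.3), "ellipticity")
})

test_that("cell summary statistics", {
  v <- c(0.10, 0.12, 0.13, 0.15, 0.20)
  s <- summarizeCell(v, binWidth = 0.01)
  expect_equal(s$mean, mean(v))
  expect_equal(s$sd, sd(v))
  expect_equal(s$sem, sd(v) / sqrt(5))
  expect_equal(s$n, 5)
  expect_equal(sum(s$histogram$count), 5)
  expect_error(summarizeCell(numeric()), "empty")
})

# tiny hand-built scene for ratio mechanics: 8x10x10 grid, bath at y<=3,
# cell y>=4, SS at y=4, two TT voxels inside
tinyMaskSet <- function(dims = c(8L, 10L, 10L)) {
  cell <- array(FALSE, dims); cell[, 5:10, ] <- TRUE
  bath <- array(FALSE, dims); bath[, 1:2, ] <- TRUE
  ss <- array(FALSE, dims); ss[, 4, ] <- TRUE
  tt <- array(FALSE, dims)
  tt[4, 8, 4:7] <- TRUE
  cyto <- cell & !ss & !tt
  cyto[, 8, ] <- FALSE  # keep a gap so cytosol is not adjacent to TT row
  new("MaskSet", cell = cell, cytosol = cyto, bath = bath,
      membraneSkeleton = tt, ssSkeleton = ss, ttSkeleton = tt,
      voxelSize = c(0.18, 0.06, 0.06))
}

test_that("V:SA of identical channels is the ratio of normalization constants", {
  ms <- tinyMaskSet()
  arr <- array(runif(prod(dim(ms@cell)), 0.5, 2), dim(ms@cell))
  vi <- volumeImage(arr, voxelSize(ms))
  psf <- psfSpec(0.6, state = "symmetrized")
  pair <- normalizePair(vi, vi, ms, psf)
  vmap <- computeVSA(pair, ms@ttSkeleton, floorFrac = 0)
  expect_equal(vsaValues(vmap),
               rep(pair@constants$ssRef / pair@constants$bathRef, 4),
               tolerance = 1e-12)
})

test_that("membrane floor drops near-zero-membrane voxels and counts them", {
  ms <- tinyMaskSet()
  vol <- array(1, dim(ms@cell))
  mem <- array(1, dim(ms@cell))
  mem[4, 8, 4] <- 1e-6   # one skeleton voxel with no membrane signal
  psf <- psfSpec(0.6, state = "symmetrized")
  pair <- new("NormalizedPair",
              volume = volumeImage(vol, voxelSize(ms)),
              membrane = volumeImage(mem, voxelSize(ms)),
              psf = psf, constants = list(bathRef = 1, ssRef = 1),
              provenance = list())
  vmap <- computeVSA(pair, ms@ttSkeleton)
  expect_equal(vmap@dropped, 1L)
  expect_equal(vsaSummary(vmap)$n, 3L)
  expect_error(computeVSA(pair, array(FALSE, dim(vol))), "empty")
})

test_that("channel correlation equals a rank-then-Pearson oracle", {
  ms <- tinyMaskSet(dims = c(8L, 10L, 30L))
  ms@ttSkeleton[] <- FALSE; ms@ttSkeleton[4, 8, 3:28] <- TRUE
  set.seed(11)
  n <- sum(ms@ttSkeleton)
  a <- array(0, dim(ms@cell)); b <- array(0, dim(ms@cell))
  av <- runif(n); bv <- av + rnorm(n, 0, 0.2)
  a[ms@ttSkeleton] <- av; b[ms@ttSkeleton] <- bv
  psf <- psfSpec(0.6, state = "symmetrized")
  pair <- new("NormalizedPair", volume = volumeImage(a, voxelSize(ms)),
              membrane = volumeImage(b, voxelSize(ms)), psf = psf,
              constants = list(), provenance = list())
  cc <- channelCorrelation(pair, ms@ttSkeleton)
  oracle <- cor(rank(av), rank(bv), method = "pearson")
  expect_equal(cc$rho, oracle, tolerance = 1e-12)
  # perfectly monotone and reversed pairs
  b2 <- a; b2[ms@ttSkeleton] <- exp(av)
  expect_equal(channelCorrelation(
    new("NormalizedPair", volume = volumeImage(a, voxelSize(ms)),
        membrane = volumeImage(b2, voxelSize(ms)), psf = psf,
        constants = list(), provenance = list()), ms@ttSkeleton)$rho, 1)
  b3 <- a; b3[ms@ttSkeleton] <- -av
  expect_equal(channelCorrelation(
    new("NormalizedPair", volume = volumeImage(a, voxelSize(ms)),
        membrane = volumeImage(b3, voxelSize(ms)), psf = psf,
        constants = list(), provenance = list()), ms@ttSkeleton)$rho, -1)
})
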