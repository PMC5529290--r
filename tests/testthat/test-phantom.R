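# Forward simulator: conservation, determinism, symmetry, bead stacks.

test_that("empty half-space scene: far bath equals the bath amplitude and the
           plane sits at 0.5", {
  psf <- isoPSF()
  hs <- renderHalfspaceCalibration(psf, gridDim = c(16L, 128L, 24L))
  vol <- imgData(hs$volume)
  pos <- hs$spec@surfacePosition
  ys <- (seq_len(128) - 0.5) * 0.06
  # far bath (> 3 FWHM from the plane): constant = bath amplitude
  far <- which(ys < pos - 1.8)
  expect_equal(max(abs(vol[, far, ] - 1)), 0, tolerance = 1e-6)
  # deep cell: zero
  deep <- which(ys > pos + 1.8)
  expect_equal(max(abs(vol[, deep, ])), 0, tolerance = 1e-6)
  # at the plane layer: 0.5 by symmetry of the blurred step
  jp <- round(pos / 0.06 + 0.5)
  expect_equal(mean(vol[, jp, ]), 0.5, tolerance = 1e-6)
  # membrane peak equals the detector-box average of the 1D Gaussian
  # line-spread 1/(sigma sqrt(2 pi)) over the 0.06 um voxel
  sig <- fwhmToSigma(0.6)
  boxPeak <- (pnorm(0.03 / sig) - pnorm(-0.03 / sig)) / 0.06
  expect_equal(mean(imgData(hs$membrane)[, jp, ]), boxPeak, tolerance = 1e-3)
})

test_that("integrated signals equal the true geometry (convolution conserves
           mass)", {
  spec <- cylinderSpec(0.3, "x", gridDim = c(32L, 128L, 96L))
  out <- renderPhantom(spec, rawPSF())
  tr <- out$truth
  voxvol <- prod(spec@voxelSize)
  # volume channel minus the bath half-space baseline = luminal volume
  bathOnly <- phantomSpec(gridDim = c(32L, 128L, 96L),
                          voxelSize = spec@voxelSize, surfaceAxis = "y",
                          surfacePosition = spec@surfacePosition)
  base <- renderPhantom(bathOnly, rawPSF())
  lumSignal <- (sum(imgData(out$volume)) - sum(imgData(base$volume))) * voxvol
  expect_equal(lumSignal, tr@ttLuminalVolume_um3,
               tolerance = 0.02 * tr@ttLuminalVolume_um3)
  # analytic cylinder volume and membrane area
  tb <- spec@tubules[[1]]
  L <- sqrt(sum((tb$centerline[2, ] - tb$centerline[1, ])^2))
  expect_equal(tr@ttLuminalVolume_um3, pi * 0.15^2 * L, tolerance = 1e-9)
  expect_equal(tr@ttMembraneArea_um2, pi * 0.3 * L, tolerance = 1e-9)
  # membrane channel integral = plane area + tubule area (unit density)
  memSignal <- sum(imgData(out$membrane)) * voxvol
  planeArea <- 32 * 0.18 * 96 * 0.06
  expect_equal(memSignal, planeArea + tr@ttMembraneArea_um2,
               tolerance = 0.02 * (planeArea + tr@ttMembraneArea_um2))
})

test_that("rendering is bit-reproducible under a fixed seed", {
  spec <- cylinderSpec(0.25, "x", gridDim = c(24L, 96L, 64L))
  spec@noise <- list(type = "poisson", scale = 500)
  spec@seed <- 7L
  a <- renderPhantom(spec, rawPSF())
  b <- renderPhantom(spec, rawPSF())
  expect_identical(imgData(a$volume), imgData(b$volume))
  expect_identical(imgData(a$membrane), imgData(b$membrane))
  # different seed changes the noise
  spec@seed <- 8L
  c <- renderPhantom(spec, rawPSF())
  expect_false(identical(imgData(a$volume), imgData(c$volume)))
})

test_that("an in-plane 90-degree rotation of the scene rotates the output", {
  # square lateral grid, surface along y; tubule along x vs the same tubule
  # along y is not symmetric (the surface breaks it), so rotate tubule and
  # surface together: compare scene (surface y, tube x) transposed in (y,x)
  # with scene (surface x, tube y)
  gd <- c(16L, 96L, 96L); vs <- c(0.18, 0.06, 0.06)
  pos <- (38 + 0.5) * 0.06
  t1 <- straightTubule(from = c(1.44, 4.0, 1.2), to = c(1.44, 4.0, 4.56),
                       diameter = 0.2)
  s1 <- phantomSpec(gridDim = gd, voxelSize = vs, surfaceAxis = "y",
                    surfacePosition = pos, tubules = list(t1))
  t2 <- straightTubule(from = c(1.44, 1.2, 4.0), to = c(1.44, 4.56, 4.0),
                       diameter = 0.2)
  s2 <- phantomSpec(gridDim = gd, voxelSize = vs, surfaceAxis = "x",
                    surfacePosition = pos, tubules = list(t2))
  psf <- isoPSF()
  r1 <- renderPhantom(s1, psf)
  r2 <- renderPhantom(s2, psf)
  expect_equal(aperm(imgData(r1$volume), c(1, 3, 2)), imgData(r2$volume),
               tolerance = 1e-9)
  expect_equal(aperm(imgData(r1$membrane), c(1, 3, 2)), imgData(r2$membrane),
               tolerance = 1e-9)
  expect_equal(sum(imgData(r1$volume)), sum(imgData(r2$volume)),
               tolerance = 1e-9)
})

test_that("scene validation rejects bad tubules and under-sampled PSFs", {
  gd <- c(16L, 96L, 64L)
  outside <- straightTubule(from = c(1.44, 4.0, -2), to = c(1.44, 4.0, 2),
                            diameter = 0.2)
  sp <- phantomSpec(gridDim = gd, tubules = list(outside))
  expect_error(renderPhantom(sp, rawPSF()), "outside the image grid")
  inBath <- straightTubule(from = c(1.44, 0.5, 1), to = c(1.44, 0.5, 3),
                           diameter = 0.2)
  sp2 <- phantomSpec(gridDim = gd, tubules = list(inBath))
  expect_error(renderPhantom(sp2, rawPSF()), "outside the cell")
  # FWHM below 2 voxels on z
  expect_error(renderPhantom(phantomSpec(gridDim = gd),
                             psfSpec(c(0.25, 0.25, 0.3))), "under-sampled")
  expect_error(phantomSpec(gridDim = gd, tubules = list(
    straightTubule(from = c(1, 4, 1), to = c(1, 4, 2), diameter = 0.2,
                   ellipticity = 1.2))))
})

test_that("bead stacks blur a sphere with the PSF", {
  psf <- rawPSF()
  # point-like bead: image FWHM = PSF FWHM within half a voxel per axis
  tiny <- renderBeadStack(psf, beadDiameter_um = 0.05)
  fw <- TubuleVSA:::stackFWHM(imgData(tiny), voxelSize(tiny))
  expect_lt(abs(fw[1] - 0.60), 0.09)
  expect_lt(abs(fw[2] - 0.25), 0.03)
  expect_lt(abs(fw[3] - 0.25), 0.03)
  # 0.17 um bead: sphere broadening frozen from a direct numerical
  # convolution oracle (fine-grid separable Gaussian of the sphere
  # indicator): FWHM (z, y, x) = (0.607, 0.266, 0.266) um
  bead <- renderBeadStack(psf, beadDiameter_um = 0.17)
  fb <- TubuleVSA:::stackFWHM(imgData(bead), voxelSize(bead))
  expect_lt(abs(fb[1] - 0.607), 0.09)
  expect_lt(abs(fb[2] - 0.266), 0.03)
  expect_lt(abs(fb[3] - 0.266), 0.03)
  # deterministic (no noise source at all)
  expect_identical(imgData(bead), imgData(renderBeadStack(psf, 0.17)))
  expect_error(renderBeadStack(psf, beadDiameter_um = 5,
                               gridDim = c(16L, 32L, 32L)), "larger")
})

test_that("groove corrugation preserves integrated membrane area", {
  spec <- phantomSpec(gridDim = c(16L, 96L, 160L),
                      surfacePosition = (38 + 0.5) * 0.06,
                      grooveAmplitude = 0.25, groovePeriod = 1.8)
  out <- renderPhantom(spec, isoPSF())
  voxvol <- prod(spec@voxelSize)
  # corrugated area exceeds the flat cross-section, by the arc-length factor
  flat <- 16 * 0.18 * 160 * 0.06
  arcFactor <- pracma::quad(function(x)
    sqrt(1 + (2 * pi * 0.25 / 1.8 * cos(2 * pi * x / 1.8))^2), 0, 1.8) / 1.8
  expect_equal(sum(imgData(out$membrane)) * voxvol, flat * arcFactor,
               tolerance = 0.02 * flat * arcFactor)
})
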