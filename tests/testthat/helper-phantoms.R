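# Shared phantom builders. Grids are kept small enough for routine test
# runs; the scene geometry (voxel sizes, PSF, surface placement) mirrors the
# package defaults: 60 nm lateral / 180 nm axial voxels, raw PSF FWHM
# 0.25/0.25/0.60 um (symmetrized 0.6 um isotropic).

rawPSF <- function() psfSpec(c(0.25, 0.25, 0.60))
isoPSF <- function(f = 0.6) psfSpec(f, state = "symmetrized")

# voxel-center position along an axis (1-based voxel j)
vcenter <- function(j, vs) (j - 0.5) * vs

# a half-space cell (surface plane orthogonal to y on a voxel-center layer)
# with one straight interior tubule; orient "x" = axial (along the long
# axis), "z" = transverse (along the optical axis)
cylinderSpec <- function(D, orient = "x", gridDim = c(48L, 128L, 144L),
                         voxelSize = c(0.18, 0.06, 0.06), depth_um = 2.1,
                         ellipticity = 1, majorAxis = c(1, 0, 0)) {
  pos <- vcenter(49, voxelSize[2])              # 2.91 um
  yc <- pos + depth_um
  yc <- vcenter(round(yc / voxelSize[2] + 0.5), voxelSize[2])
  if (orient == "x") {
    zc <- vcenter(floor(gridDim[1] / 2) + 1L, voxelSize[1])
    xext <- gridDim[3] * voxelSize[3]
    tb <- straightTubule(from = c(zc, yc, 1.0), to = c(zc, yc, xext - 1.0),
                         diameter = D, ellipticity = ellipticity,
                         majorAxis = majorAxis)
  } else {
    xc <- vcenter(floor(gridDim[3] / 2) + 1L, voxelSize[3])
    zext <- gridDim[1] * voxelSize[1]
    tb <- straightTubule(from = c(1.0, yc, xc), to = c(zext - 1.0, yc, xc),
                         diameter = D, ellipticity = ellipticity,
                         majorAxis = majorAxis)
  }
  phantomSpec(gridDim = gridDim, voxelSize = voxelSize, surfaceAxis = "y",
              surfacePosition = pos, tubules = list(tb))
}

# full pipeline on a phantom spec; returns the pieces tests poke at
runPhantomPipeline <- function(spec, psf = rawPSF()) {
  rend <- renderPhantom(spec, psf)
  masks <- buildMaskSet(rend$membrane, rend$volume, psf)
  pair <- preprocessChannels(rend$membrane, rend$volume, masks, psf)
  vmap <- computeVSA(pair, masks@ttSkeleton)
  list(rend = rend, masks = masks, pair = pair, vmap = vmap)
}

# true-centerline voxel indices of a straight tubule (n x 3, 1-based)
centerlineIndices <- function(spec, tubule) {
  vs <- spec@voxelSize
  P <- tubule$centerline
  d <- P[2, ] - P[1, ]
  L <- sqrt(sum(d^2))
  tt <- seq(0.2, L - 0.2, by = min(vs))
  pts <- sweep(outer(tt, d / L), 2, P[1, ], "+")
  idx <- unique(round(sweep(pts, 2, vs, "/") + 0.5))
  idx[apply(idx >= 1, 1, all) &
        idx[, 1] <= spec@gridDim[1] & idx[, 2] <= spec@gridDim[2] &
        idx[, 3] <= spec@gridDim[3], , drop = FALSE]
}

# mask with TRUE at given (z,y,x) indices
indicesToMask <- function(idx, dims) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  m
}
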