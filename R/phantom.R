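#' Describe a straight (or polyline) tubule for the phantom
#'
#' @param from,to endpoints in micrometres, (z, y, x) order. Alternatively
#'   supply `centerline` directly.
#' @param centerline numeric matrix (n x 3) of polyline points (z, y, x), um.
#' @param diameter tubule diameter in um. For elliptical cross-sections this
#'   is the major axis; the minor axis is `ellipticity * diameter`.
#' @param ellipticity minor/major axis ratio in (0, 1]; 1 = circular.
#' @param majorAxis direction (z, y, x) of the cross-section major axis for
#'   elliptical tubules; projected into the plane normal to the centerline.
#' @return a list understood by [phantomSpec()].
#' @export
straightTubule <- function(from = NULL, to = NULL, diameter, ellipticity = 1,
                           majorAxis = c(1, 0, 0), centerline = NULL) {
  if (is.null(centerline)) centerline <- rbind(from, to)
  centerline <- matrix(as.numeric(centerline), ncol = 3)
  stopifnot(nrow(centerline) >= 2, diameter > 0,
            ellipticity > 0, ellipticity <= 1)
  list(centerline = centerline, diameter = diameter,
       ellipticity = ellipticity, majorAxis = as.numeric(majorAxis))
}

#' Construct a PhantomSpec
#'
#' Defaults mirror the imaging geometry the method was developed for:
#' 60 nm voxels in the focal plane (x-y) and 180 nm along the optical axis
#' (z), a 256 x 256 x 64 (x, y, z) field of view, a half-space cell whose
#' surface plane is orthogonal to y (a lateral axis, so the surface normal
#' lies in the focal plane as for the side wall of an imaged myocyte), unit
#' bath amplitude and unit membrane surface density, and no noise.
#'
#' @param gridDim voxels per axis, (z, y, x).
#' @param voxelSize um per axis, (z, y, x).
#' @param surfaceAxis axis orthogonal to the cell surface plane; the cell
#'   occupies the high-coordinate side.
#' @param surfacePosition plane position (um); default: a voxel-center layer
#'   near 40% of the axis extent.
#' @param grooveAmplitude,groovePeriod sinusoidal surface corrugation
#'   (z-grooves) along the cell long axis, um; amplitude 0 disables.
#' @param tubules list of [straightTubule()] entries.
#' @param bathAmplitude,membraneDensity dye amplitudes (arbitrary units).
#' @param noise list(type = "none"|"gaussian"|"poisson", sd = , scale = ).
#' @param seed RNG seed for the noise model.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(gridDim = c(64L, 256L, 256L),
                        voxelSize = c(0.18, 0.06, 0.06),
                        surfaceAxis = "y", surfacePosition = NULL,
                        grooveAmplitude = 0, groovePeriod = 1.8,
                        tubules = list(),
                        bathAmplitude = 1, membraneDensity = 1,
                        noise = list(type = "none"), seed = 1L) {
  ai <- match(surfaceAxis, c("z", "y", "x"))
  if (is.null(surfacePosition)) {
    j <- floor(gridDim[ai] * 0.4)
    surfacePosition <- (j + 0.5) * voxelSize[ai]
  }
  new("PhantomSpec", gridDim = as.integer(gridDim),
      voxelSize = setNames(as.numeric(voxelSize), c("z", "y", "x")),
      surfaceAxis = surfaceAxis, surfacePosition = surfacePosition,
      grooveAmplitude = grooveAmplitude, groovePeriod = groovePeriod,
      tubules = tubules, bathAmplitude = bathAmplitude,
      membraneDensity = membraneDensity, noise = noise,
      seed = as.integer(seed))
}

# long axis of the phantom cell: x unless the surface is orthogonal to x
phantomLongAxis <- function(spec) if (spec@surfaceAxis == "x") "y" else "x"

# surface height h(s) along the surface axis as a function of the
# long-axis coordinate s
surfaceHeight <- function(spec, s) {
  spec@surfacePosition +
    if (spec@grooveAmplitude > 0)
      spec@grooveAmplitude * sin(2 * pi * s / spec@groovePeriod) else 0
}

#' Perimeter of an ellipse
#'
#' Complete-elliptic-integral perimeter of an ellipse with the given
#' semi-axes.
#'
#' @param a,b semi-axes (a >= b), any length unit.
#' @return perimeter in the same unit.
#' @export
ellipsePerimeter <- function(a, b) {
  stopifnot(a > 0, b > 0, b <= a + 1e-12)
  m <- 1 - (b / a)^2
  4 * a * pracma::ellipke(m)$e
}

# For query points Q (m x 3, um) against one tubule: returns list(rho, rp)
# where rho is the elliptical normalized radius (<= 1 means inside the
# lumen) minimized over all flat-ended segments (Inf where no segment
# covers the point axially) and rp the physical radial distance from the
# centerline for the minimizing segment.
tubuleRho <- function(Q, tubule) {
  P <- tubule$centerline
  a <- tubule$diameter / 2
  b <- a * tubule$ellipticity
  rho <- rep(Inf, nrow(Q))
  rp <- rep(Inf, nrow(Q))
  for (i in seq_len(nrow(P) - 1)) {
    A <- P[i, ]; B <- P[i + 1, ]
    d <- B - A; L <- sqrt(sum(d^2))
    if (L < 1e-12) next
    dn <- d / L
    # local cross-section frame
    u <- tubule$majorAxis - sum(tubule$majorAxis * dn) * dn
    if (sqrt(sum(u^2)) < 1e-9) {
      u <- c(0, 1, 0) - sum(c(0, 1, 0) * dn) * dn
      if (sqrt(sum(u^2)) < 1e-9) u <- c(1, 0, 0) - sum(c(1, 0, 0) * dn) * dn
    }
    u <- u / sqrt(sum(u^2))
    v <- c(dn[2] * u[3] - dn[3] * u[2],
           dn[3] * u[1] - dn[1] * u[3],
           dn[1] * u[2] - dn[2] * u[1])
    rel <- sweep(Q, 2, A)
    t <- rel %*% dn
    inseg <- t >= 0 & t <= L
    if (!any(inseg)) next
    rad <- rel - t %*% t(dn)
    ru <- rad %*% u
    rv <- rad %*% v
    r2 <- sqrt((ru / a)^2 + (rv / b)^2)
    upd <- inseg & r2 < rho
    rho[upd] <- r2[upd]
    rp[upd] <- sqrt(ru[upd]^2 + rv[upd]^2)
  }
  list(rho = rho, rp = rp)
}

# voxel bounding box (1-based index ranges) around a tubule with margin (um)
tubuleBox <- function(spec, tubule, margin) {
  lo <- apply(tubule$centerline, 2, min) - margin
  hi <- apply(tubule$centerline, 2, max) + margin
  vs <- spec@voxelSize
  i0 <- pmax(1L, floor(lo / vs - 0.5) + 1L)
  i1 <- pmin(spec@gridDim, ceiling(hi / vs + 0.5))
  list(i0 = as.integer(i0), i1 = as.integer(i1))
}

# sub-voxel center coordinates for a box of voxels; nsub per axis chosen so
# sub-cells are approximately cubes of the finest voxel pitch / 3
subGrid <- function(spec, box) {
  vs <- spec@voxelSize
  nsub <- pmax(3L, round(vs / min(vs) * 3))
  axes <- lapply(1:3, function(ax) {
    idx <- box$i0[ax]:box$i1[ax]
    off <- ((seq_len(nsub[ax]) - 0.5) / nsub[ax] - 0.5) * vs[ax]
    list(centers = (idx - 0.5) * vs[ax], off = off, idx = idx)
  })
  list(axes = axes, nsub = nsub)
}

# rasterize one tubule into lumen occupancy and membrane shell fields over
# its bounding box; returns list(idx (n x 3 voxel indices), lumen, shell)
rasterizeTubule <- function(spec, tubule) {
  a <- tubule$diameter / 2
  margin <- a + 2 * max(spec@voxelSize)
  box <- tubuleBox(spec, tubule, margin)
  sg <- subGrid(spec, box)
  nv <- box$i1 - box$i0 + 1L
  # all sub-voxel coordinates, grouped by voxel
  coord1 <- lapply(1:3, function(ax)
    rep(sg$axes[[ax]]$centers, each = sg$nsub[ax]) + sg$axes[[ax]]$off)
  nz <- length(coord1[[1]]); ny <- length(coord1[[2]]); nx <- length(coord1[[3]])
  Q <- cbind(rep(coord1[[1]], times = ny * nx),
             rep(rep(coord1[[2]], each = nz), times = nx),
             rep(coord1[[3]], each = nz * ny))
  tr <- tubuleRho(Q, tubule)
  # anti-aliasing support ~2.5 sub-cells: wide enough that ray-sampling of
  # the shell is alias-free, narrow enough (<< PSF sigma) not to widen it
  tphys <- min(spec@voxelSize) / 3 * 2.5
  # signed distance to the wall along the radial ray: d = rp (1 - 1/rho)
  # (exact for circles, first-order for ellipses); anti-aliased weights
  # avoid sub-grid aliasing of thin shells
  d <- ifelse(is.finite(tr$rho),
              ifelse(tr$rho > 0, tr$rp * (1 - 1 / tr$rho), -a), Inf)
  lum <- pmin(1, pmax(0, 0.5 - d / tphys))
  shl <- pmax(0, 1 - abs(d) / tphys)
  # fold sub-voxels back onto voxels
  dim(lum) <- c(nz, ny, nx); dim(shl) <- c(nz, ny, nx)
  fold3 <- function(arr) {
    d <- dim(arr)
    a1 <- array(arr, c(sg$nsub[1], nv[1], d[2], d[3]))
    a1 <- colMeans(a1)                                # (nv1, ny, nx)
    a2 <- aperm(a1, c(2, 1, 3))
    a2 <- array(a2, c(sg$nsub[2], nv[2], nv[1], d[3]))
    a2 <- colMeans(a2)                                # (nv2, nv1, nx)
    a3 <- aperm(a2, c(3, 1, 2))
    a3 <- array(a3, c(sg$nsub[3], nv[3], nv[2], nv[1]))
    a3 <- colMeans(a3)                                # (nv3, nv2, nv1)
    aperm(a3, c(3, 2, 1))                             # (nv1, nv2, nv3)
  }
  list(box = box, lumen = fold3(lum), shell = fold3(shl))
}

# polyline length in um
polylineLength <- function(P) {
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

tubuleOrientationDeg <- function(tubule, longAxisIdx) {
  P <- tubule$centerline
  d <- P[nrow(P), ] - P[1, ]
  asin(min(1, abs(d[longAxisIdx]) / sqrt(sum(d^2)))) * 180 / pi
}

# extracellular (bath-side) occupancy of the half-space scene, before tubules
bathOccupancy <- function(spec) {
  vs <- spec@voxelSize
  nd <- spec@gridDim
  ai <- match(spec@surfaceAxis, c("z", "y", "x"))
  occ <- array(0, nd)
  if (spec@grooveAmplitude == 0) {
    centers <- (seq_len(nd[ai]) - 0.5) * vs[ai]
    frac <- pmin(1, pmax(0, (spec@surfacePosition - (centers - vs[ai] / 2)) / vs[ai]))
    occ <- array(0, nd)
    if (ai == 1) occ[] <- frac
    else if (ai == 2) occ[] <- rep(rep(frac, each = nd[1]), times = nd[3])
    else occ[] <- rep(frac, each = nd[1] * nd[2])
  } else {
    li <- match(phantomLongAxis(spec), c("z", "y", "x"))
    A <- spec@grooveAmplitude
    band <- c(spec@surfacePosition - A - vs[ai],
              spec@surfacePosition + A + vs[ai])
    centers_a <- (seq_len(nd[ai]) - 0.5) * vs[ai]
    # far bath / deep cell decided per voxel; band voxels supersampled
    nsub <- pmax(3L, round(vs / min(vs) * 3))
    centers_l <- (seq_len(nd[li]) - 0.5) * vs[li]
    off_a <- ((seq_len(nsub[ai]) - 0.5) / nsub[ai] - 0.5) * vs[ai]
    off_l <- ((seq_len(nsub[li]) - 0.5) / nsub[li] - 0.5) * vs[li]
    # fraction of (a, l) sub-cells on the bath side, per (a, l) voxel pair
    fr <- matrix(0, nd[ai], nd[li])
    for (ia in seq_len(nd[ai])) {
      ca <- centers_a[ia]
      if (ca + vs[ai] / 2 <= band[1]) { fr[ia, ] <- 1; next }
      if (ca - vs[ai] / 2 >= band[2]) { fr[ia, ] <- 0; next }
      sa <- ca + off_a
      for (il in seq_len(nd[li])) {
        sl <- centers_l[il] + off_l
        h <- surfaceHeight(spec, sl)
        fr[ia, il] <- mean(outer(sa, h, "<"))
      }
    }
    # expand fr over the third axis
    oi <- setdiff(1:3, c(ai, li))
    perm <- order(c(ai, li, oi))
    full <- array(rep(fr, times = nd[oi]), c(nd[ai], nd[li], nd[oi]))
    occ <- aperm(full, perm)
  }
  occ
}

# surface membrane field (area density rasterized onto the grid), and the
# true surface area within the grid
surfaceMembrane <- function(spec) {
  vs <- spec@voxelSize
  nd <- spec@gridDim
  ai <- match(spec@surfaceAxis, c("z", "y", "x"))
  oth <- setdiff(1:3, ai)
  crossArea <- prod(nd[oth] * vs[oth])
  fld <- array(0, nd)
  if (spec@grooveAmplitude == 0) {
    # tent interpolation of an infinitely thin plane onto the voxel lattice
    pos_idx <- spec@surfacePosition / vs[ai] + 0.5   # in voxel-index units
    j0 <- floor(pos_idx); w1 <- pos_idx - j0
    prof <- numeric(nd[ai])
    if (j0 >= 1 && j0 <= nd[ai]) prof[j0] <- (1 - w1)
    if (j0 + 1 >= 1 && j0 + 1 <= nd[ai]) prof[j0 + 1] <- w1
    prof <- prof * spec@membraneDensity / vs[ai]
    if (ai == 1) fld[] <- prof
    else if (ai == 2) fld[] <- rep(rep(prof, each = nd[1]), times = nd[3])
    else fld[] <- rep(prof, each = nd[1] * nd[2])
    area <- crossArea
  } else {
    li <- match(phantomLongAxis(spec), c("z", "y", "x"))
    A <- spec@grooveAmplitude
    nsub <- pmax(3L, round(vs / min(vs) * 3))
    tphys <- min(vs) / 3
    centers_a <- (seq_len(nd[ai]) - 0.5) * vs[ai]
    centers_l <- (seq_len(nd[li]) - 0.5) * vs[li]
    off_a <- ((seq_len(nsub[ai]) - 0.5) / nsub[ai] - 0.5) * vs[ai]
    off_l <- ((seq_len(nsub[li]) - 0.5) / nsub[li] - 0.5) * vs[li]
    band <- c(spec@surfacePosition - A - vs[ai], spec@surfacePosition + A + vs[ai])
    fr <- matrix(0, nd[ai], nd[li])
    for (ia in seq_len(nd[ai])) {
      ca <- centers_a[ia]
      if (ca + vs[ai] / 2 < band[1] || ca - vs[ai] / 2 > band[2]) next
      sa <- ca + off_a
      for (il in seq_len(nd[li])) {
        sl <- centers_l[il] + off_l
        h <- surfaceHeight(spec, sl)
        fr[ia, il] <- mean(abs(outer(sa, h, "-")) < tphys / 2)
      }
    }
    oi <- setdiff(1:3, c(ai, li))
    perm <- order(c(ai, li, oi))
    fld <- aperm(array(rep(fr, times = nd[oi]), c(nd[ai], nd[li], nd[oi])), perm)
    # true corrugated area: per unit long-axis length, x the other extent
    grid_l <- seq(0, nd[li] * vs[li], length.out = 4097)
    dh <- 2 * pi * A / spec@groovePeriod * cos(2 * pi * grid_l / spec@groovePeriod)
    arc <- pracma::trapz(grid_l, sqrt(1 + dh^2))
    area <- arc * nd[oi] * vs[oi]
    tot <- sum(fld) * prod(vs)
    if (tot > 0) fld <- fld * (area * spec@membraneDensity / tot)
  }
  list(field = fld, area = area)
}

checkTubuleInside <- function(spec, tubule) {
  vs <- spec@voxelSize
  ext <- spec@gridDim * vs
  a <- tubule$diameter / 2
  P <- tubule$centerline
  if (any(sweep(P, 2, ext - a) > 0) || any(P < a))
    stop("tubule extends outside the image grid")
  ai <- match(spec@surfaceAxis, c("z", "y", "x"))
  li <- match(phantomLongAxis(spec), c("z", "y", "x"))
  h <- surfaceHeight(spec, P[, li])
  if (any(P[, ai] < h - 1e-9))
    stop("tubule centerline lies outside the cell region")
  invisible(TRUE)
}

applyNoise <- function(arr, noise, seed) {
  type <- noise$type %||% "none"
  if (type == "none") return(arr)
  withSeed(seed, {
    if (type == "gaussian") {
      arr + rnorm(length(arr), 0, noise$sd)
    } else if (type == "poisson") {
      sc <- noise$scale
      out <- rpois(length(arr), pmax(arr, 0) * sc) / sc
      dim(out) <- dim(arr)
      out
    } else stop("unknown noise type: ", type)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a dual-dye phantom
#'
#' Forward-simulates confocal imaging of a half-space cell with tubules
#' invaginating from (or lying beneath) its surface: the volume channel is
#' the indicator of extracellular space (bath plus tubule lumina) times the
#' bath amplitude; the membrane channel is a surface-density field on the
#' cell surface plane and tubule walls. Both are convolved with the
#' anisotropic Gaussian PSF; noise (if any) is applied after blurring.
#'
#' Membrane shells are rasterized by super-sampling a thin shell and then
#' normalized so each shell integrates to its true area times the surface
#' density, so that shell thickness does not leak into V:SA.
#'
#' @param spec a [PhantomSpec-class].
#' @param psf a [PSFSpec-class]; FWHM must be at least 2 voxels per axis.
#' @return list(membrane = [VolumeImage-class], volume = [VolumeImage-class],
#'   truth = [PhantomTruth-class]).
#' @examples
#' sp <- phantomSpec(gridDim = c(16, 48, 32), tubules = list())
#' out <- renderPhantom(sp, psfSpec(c(0.25, 0.25, 0.6)))
#' out$volume
#' @export
renderPhantom <- function(spec, psf) {
  validObject(spec)
  vs <- spec@voxelSize
  fw <- psfFWHM(psf)
  if (any(fw < 2 * vs))
    stop("PSF FWHM under-sampled: need FWHM >= 2 voxels on every axis")
  for (tb in spec@tubules) checkTubuleInside(spec, tb)

  # Render on an internal grid refined to the finest voxel pitch, blur
  # there, and box-average back down: blurring after rasterization onto the
  # anisotropic acquisition grid would apply the detector box twice along
  # the coarse (z) axis and misquote sharp structures by several percent.
  refine <- as.integer(round(vs / min(vs)))
  fine <- spec
  fine@gridDim <- spec@gridDim * refine
  fine@voxelSize <- setNames(vs / refine, c("z", "y", "x"))
  spec <- fine

  occ <- bathOccupancy(spec)
  mem <- surfaceMembrane(spec)
  memField <- mem$field
  voxvol <- prod(spec@voxelSize)
  li <- match(phantomLongAxis(spec), c("z", "y", "x"))

  rows <- list()
  ttArea <- 0; ttVol <- 0
  for (tb in spec@tubules) {
    ras <- rasterizeTubule(spec, tb)
    L <- polylineLength(tb$centerline)
    aa <- tb$diameter / 2; bb <- aa * tb$ellipticity
    areaTrue <- ellipsePerimeter(aa, bb) * L
    volTrue <- pi * aa * bb * L
    zi <- ras$box$i0[1]:ras$box$i1[1]
    yi <- ras$box$i0[2]:ras$box$i1[2]
    xi <- ras$box$i0[3]:ras$box$i1[3]
    # normalize first moments to the analytic geometry so that sub-voxel
    # alignment of thin tubules cannot bias integrated lumen volume
    lum <- ras$lumen
    lumTot <- sum(lum) * voxvol
    if (lumTot > 0) lum <- lum * (volTrue / lumTot)
    occ[zi, yi, xi] <- pmax(occ[zi, yi, xi], lum)
    shl <- ras$shell
    tot <- sum(shl) * voxvol
    if (tot > 0) shl <- shl * (areaTrue * spec@membraneDensity / tot)
    memField[zi, yi, xi] <- memField[zi, yi, xi] + shl
    rows[[length(rows) + 1]] <- data.frame(
      diameter_um = tb$diameter, ellipticity = tb$ellipticity,
      orientation_deg = tubuleOrientationDeg(tb, li),
      length_um = L, area_um2 = areaTrue, volume_um3 = volTrue)
    ttArea <- ttArea + areaTrue; ttVol <- ttVol + volTrue
  }

  volField <- occ * spec@bathAmplitude
  sig <- psfSigma(psf)
  volBlur <- boxDownsample(gaussBlur(volField, sig, spec@voxelSize), refine)
  memBlur <- boxDownsample(gaussBlur(memField, sig, spec@voxelSize), refine)
  volBlur <- applyNoise(volBlur, spec@noise, spec@seed)
  memBlur <- applyNoise(memBlur, spec@noise, spec@seed + 1L)

  truth <- new("PhantomTruth",
    tubules = if (length(rows)) do.call(rbind, rows) else
      data.frame(diameter_um = numeric(), ellipticity = numeric(),
                 orientation_deg = numeric(), length_um = numeric(),
                 area_um2 = numeric(), volume_um3 = numeric()),
    cellVolume_um3 = sum(1 - occ) * voxvol,
    ttMembraneArea_um2 = ttArea, ttLuminalVolume_um3 = ttVol)

  list(membrane = volumeImage(memBlur, vs),
       volume = volumeImage(volBlur, vs),
       truth = truth)
}

#' Render a fluorescent bead stack
#'
#' A sphere indicator of the given diameter, centered mid-grid, convolved
#' with the PSF. Used to exercise PSF estimation.
#'
#' @param psf [PSFSpec-class].
#' @param beadDiameter_um bead diameter (um).
#' @param gridDim,voxelSize grid geometry, (z, y, x).
#' @return [VolumeImage-class].
#' @export
renderBeadStack <- function(psf, beadDiameter_um = 0.17,
                            gridDim = c(32L, 64L, 64L),
                            voxelSize = c(0.18, 0.06, 0.06)) {
  vs <- setNames(as.numeric(voxelSize), c("z", "y", "x"))
  ext <- gridDim * vs
  if (beadDiameter_um >= min(ext) / 2)
    stop("bead larger than the grid allows")
  # fine internal grid, as in renderPhantom
  refine <- as.integer(round(vs / min(vs)))
  gdF <- gridDim * refine
  vsF <- vs / refine
  ctr <- (floor(gridDim / 2) + 0.5) * vs
  R <- beadDiameter_um / 2
  # anti-aliased sphere occupancy on the fine grid (3x supersampling)
  ni <- pmax(1L, ceiling((R + 2 * vsF) / vsF))
  c0 <- floor(ctr / vsF) + 1L
  i0 <- pmax(1L, c0 - ni); i1 <- pmin(gdF, c0 + ni)
  sub <- lapply(1:3, function(ax) {
    idx <- i0[ax]:i1[ax]
    off <- ((1:3 - 0.5) / 3 - 0.5) * vsF[ax]
    rep((idx - 0.5) * vsF[ax], each = 3) + off
  })
  nz <- length(sub[[1]]); ny <- length(sub[[2]]); nx <- length(sub[[3]])
  d2 <- outer(outer((sub[[1]] - ctr[1])^2, (sub[[2]] - ctr[2])^2, "+"),
              (sub[[3]] - ctr[3])^2, "+")
  inside <- d2 <= R^2
  nv <- i1 - i0 + 1L
  a1 <- colMeans(array(inside, c(3, nv[1], ny, nx)))
  a2 <- aperm(a1, c(2, 1, 3))
  a2 <- colMeans(array(a2, c(3, nv[2], nv[1], nx)))
  a3 <- aperm(a2, c(3, 1, 2))
  a3 <- colMeans(array(a3, c(3, nv[3], nv[2], nv[1])))
  occ <- aperm(a3, c(3, 2, 1))
  arr <- array(0, gdF)
  arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- occ
  out <- boxDownsample(gaussBlur(arr, psfSigma(psf), vsF), refine)
  volumeImage(out, vs)
}

#' Render the half-space calibration scene
#'
#' A plane cell surface with no tubules: the volume channel is a blurred
#' half-space step (extracellular side = 1) and the membrane channel a
#' blurred plane of unit surface density. At the plane the bath-normalized
#' volume signal is 0.5 by symmetry, which is the surface-sarcolemma
#' calibration point of the V:SA method.
#'
#' @param psf [PSFSpec-class] used for the blur.
#' @param gridDim,voxelSize grid geometry (z, y, x).
#' @param surfaceAxis axis orthogonal to the plane.
#' @return list(membrane, volume, spec, truth).
#' @export
renderHalfspaceCalibration <- function(psf, gridDim = c(32L, 128L, 48L),
                                       voxelSize = c(0.18, 0.06, 0.06),
                                       surfaceAxis = "y") {
  spec <- phantomSpec(gridDim = gridDim, voxelSize = voxelSize,
                      surfaceAxis = surfaceAxis, tubules = list(),
                      noise = list(type = "none"))
  out <- renderPhantom(spec, psf)
  out$spec <- spec
  out
}
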