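# skeleton voxel graph: vertices = skeleton voxels (rows of coords),
# edges between 26-adjacent voxels weighted by physical distance (um)
skeletonGraph <- function(skel, voxelSize) {
  idx <- maskIndices(skel)
  n <- nrow(idx)
  if (n == 0)
    return(list(graph = igraph::make_empty_graph(0, directed = FALSE),
                coords = idx))
  key <- (idx[, 1] - 1) + dim(skel)[1] * ((idx[, 2] - 1) +
         dim(skel)[2] * (idx[, 3] - 1))
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  # half the offsets to avoid duplicate edges
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ]
  from <- integer(); to <- integer(); w <- numeric()
  d <- dim(skel)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nk <- (nb[ok, 1] - 1) + d[1] * ((nb[ok, 2] - 1) + d[2] * (nb[ok, 3] - 1))
    hit <- match(nk, key)
    sel <- which(ok)[!is.na(hit)]
    if (!length(sel)) next
    from <- c(from, sel)
    to <- c(to, hit[!is.na(hit)])
    w <- c(w, rep(sqrt(sum((offs[r, ] * voxelSize)^2)), length(sel)))
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::E(g)$weight <- w
  list(graph = g, coords = idx)
}

#' Total skeleton length and length density
#'
#' Skeleton length is the sum of physical inter-voxel distances over a
#' minimum spanning tree of each connected component of the 26-adjacency
#' skeleton graph (exact for tree-shaped skeletons, which thinning
#' produces; anisotropy-aware: a step (dz, dy, dx) contributes
#' sqrt((dz vz)^2 + (dy vy)^2 + (dx vx)^2) um). Length density divides by
#' the cell-mask volume.
#'
#' @param ttSkel logical skeleton array.
#' @param cell logical cell mask.
#' @param voxelSize voxel sizes (z, y, x) um.
#' @return list(length_um, cellVolume_um3, density = um/um^3).
#' @export
skeletonLengthDensity <- function(ttSkel, cell, voxelSize) {
  if (!any(cell)) stop("cell mask is empty")
  cellVol <- sum(cell) * prod(voxelSize)
  if (!any(ttSkel))
    return(list(length_um = 0, cellVolume_um3 = cellVol, density = 0))
  g <- skeletonGraph(ttSkel, voxelSize)
  mst <- igraph::mst(g$graph, weights = igraph::E(g$graph)$weight)
  len <- sum(igraph::E(mst)$weight)
  list(length_um = len, cellVolume_um3 = cellVol, density = len / cellVol)
}

#' Local tubule orientation from the structure tensor of the skeleton
#'
#' For each skeleton voxel, the principal eigenvector of the second-moment
#' tensor of skeleton voxel coordinates within a spherical physical-radius
#' window gives the local tubule direction; the reported angle is measured
#' from the cell's transverse plane (0 deg = transverse, 90 deg = axial,
#' i.e. along the cell long axis).
#'
#' @param ttSkel logical skeleton array.
#' @param voxelSize voxel sizes (z, y, x) um.
#' @param radius_um window radius (um).
#' @param longAxis unit direction (z, y, x) of the cell long axis; derived
#'   from `cellMask` by PCA when NULL.
#' @param cellMask optional logical array for the long-axis PCA.
#' @return numeric vector of angles (degrees) per skeleton voxel, NA where
#'   fewer than 3 voxels fall in the window (unclassified).
#' @export
localOrientation <- function(ttSkel, voxelSize, radius_um = 0.5,
                             longAxis = NULL, cellMask = NULL) {
  idx <- maskIndices(ttSkel)
  if (nrow(idx) == 0) stop("skeleton is empty")
  if (is.null(longAxis)) {
    if (is.null(cellMask)) stop("give longAxis or cellMask")
    cidx <- maskIndices(cellMask)
    if (nrow(cidx) > 20000) cidx <- cidx[seq(1, nrow(cidx), length.out = 20000), ]
    pc <- prcomp(indexToCoord(cidx, voxelSize))
    longAxis <- pc$rotation[, 1]
  }
  u <- longAxis / sqrt(sum(longAxis^2))
  co <- indexToCoord(idx, voxelSize)
  # spatial binning for neighbor lookup
  bins <- floor(sweep(co, 2, radius_um, "/"))
  key <- paste(bins[, 1], bins[, 2], bins[, 3])
  lookup <- split(seq_len(nrow(co)), key)
  ang <- rep(NA_real_, nrow(co))
  for (i in seq_len(nrow(co))) {
    kb <- bins[i, ]
    nb <- unlist(lookup[paste(rep(kb[1] + (-1:1), times = 9),
                              rep(rep(kb[2] + (-1:1), each = 3), times = 3),
                              rep(kb[3] + (-1:1), each = 9))], use.names = FALSE)
    d2 <- rowSums(sweep(co[nb, , drop = FALSE], 2, co[i, ])^2)
    nb <- nb[d2 <= radius_um^2]
    if (length(nb) < 3) next
    pts <- sweep(co[nb, , drop = FALSE], 2, colMeans(co[nb, , drop = FALSE]))
    ev <- eigen(crossprod(pts), symmetric = TRUE)$vectors[, 1]
    ang[i] <- 90 - acos(min(1, abs(sum(ev * u)))) * 180 / pi
  }
  ang
}

#' Classify orientation angles into transverse / axial / oblique fractions
#'
#' Transverse: within 15 degrees of the transverse plane (closed interval,
#' [0, 15]); axial: within 15 degrees of the long axis ([75, 90]); oblique:
#' the remainder. Fractions are per classified skeleton voxel
#' (length-weighted, since skeleton voxels are near-equidistant samples of
#' the centerline).
#'
#' @param angles numeric degrees in [0, 90]; NA = unclassified (excluded).
#' @param tol half-width of the named classes (degrees).
#' @return named numeric (percent): transverse, axial, oblique.
#' @export
classifyOrientation <- function(angles, tol = 15) {
  a <- angles[!is.na(angles)]
  if (!length(a)) return(c(transverse = NA_real_, axial = NA_real_,
                           oblique = NA_real_))
  if (any(a < -1e-9 | a > 90 + 1e-9)) stop("angles must lie in [0, 90]")
  tr <- mean(a <= tol) * 100
  ax <- mean(a >= 90 - tol) * 100
  c(transverse = tr, axial = ax, oblique = 100 - tr - ax)
}

#' Derived TT network geometry
#'
#' Exact arithmetic on the mean diameter and length density: membrane area
#' density pi * D * L (um^2/um^3), luminal volume fraction
#' (pi * D^2 / 4) * L * 100 (% of cell volume), and -- when the total
#' membrane density is supplied -- the percent of total cell membrane in
#' TTs.
#'
#' @param meanDiameter_um mean tubule diameter D (um).
#' @param lengthDensity length density L (um/um^3).
#' @param totalMembraneDensity_um2um3 optional total cell membrane area per
#'   cell volume (um^2/um^3).
#' @return list(areaDensity_um2um3, volumeFraction_pct, membraneFraction_pct).
#' @examples
#' derivedGeometry(0.169, 0.70)        # mouse-like: 0.37, 1.6%
#' derivedGeometry(0.356, 0.27, 0.46)  # rabbit-like: 0.30, 2.7%, 65%
#' @export
derivedGeometry <- function(meanDiameter_um, lengthDensity,
                            totalMembraneDensity_um2um3 = NULL) {
  if (meanDiameter_um <= 0 || lengthDensity <= 0)
    stop("diameter and length density must be positive")
  area <- pi * meanDiameter_um * lengthDensity
  volFrac <- pi * meanDiameter_um^2 / 4 * lengthDensity * 100
  memFrac <- if (is.null(totalMembraneDensity_um2um3)) NA_real_ else {
    if (totalMembraneDensity_um2um3 <= 0)
      stop("total membrane density must be positive")
    area / totalMembraneDensity_um2um3 * 100
  }
  list(areaDensity_um2um3 = area, volumeFraction_pct = volFrac,
       membraneFraction_pct = memFrac)
}

#' Assemble NetworkStats for one cell
#'
#' @param ttSkel,cell logical arrays.
#' @param voxelSize voxel sizes (z, y, x) um.
#' @param meanDiameter_um mean TT diameter from the [VSAMap-class].
#' @param longAxis cell long axis (z, y, x); PCA of the cell mask if NULL.
#' @param totalMembraneDensity_um2um3 optional literature value.
#' @param radius_um orientation window radius.
#' @return [NetworkStats-class].
#' @export
networkStats <- function(ttSkel, cell, voxelSize, meanDiameter_um,
                         longAxis = NULL,
                         totalMembraneDensity_um2um3 = NULL,
                         radius_um = 0.5) {
  ld <- skeletonLengthDensity(ttSkel, cell, voxelSize)
  ang <- localOrientation(ttSkel, voxelSize, radius_um = radius_um,
                          longAxis = longAxis, cellMask = cell)
  fr <- classifyOrientation(ang)
  geo <- derivedGeometry(meanDiameter_um, ld$density,
                         totalMembraneDensity_um2um3)
  new("NetworkStats", lengthDensity = ld$density, fractions = fr,
      meanDiameter = meanDiameter_um, areaDensity = geo$areaDensity_um2um3,
      volumeFraction = geo$volumeFraction_pct,
      membraneFraction = geo$membraneFraction_pct)
}
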