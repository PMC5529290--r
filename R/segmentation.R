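#' Otsu intensity threshold
#'
#' Threshold maximizing the between-class variance of a 256-bin histogram
#' over the observed intensity range.
#'
#' @param image 3D array, [VolumeImage-class], or numeric vector.
#' @param within optional logical mask restricting the histogram.
#' @param nbins number of histogram bins.
#' @return the threshold (numeric). Attribute `separability` carries the
#'   between-class to total variance ratio at the optimum (1 = perfectly
#'   bimodal), useful to detect unimodal inputs.
#' @export
otsuThreshold <- function(image, within = NULL, nbins = 256L) {
  x <- if (is(image, "VolumeImage")) imgData(image) else image
  if (!is.null(within)) x <- x[within]
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop("cannot threshold a constant image")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
                     nbins), nbins)
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  w1 <- 1 - w0
  num <- (muT * w0 - mu)^2
  den <- w0 * w1
  sB <- ifelse(den > 0, num / den, 0)
  k <- which(sB == max(sB))
  k <- k[ceiling(length(k) / 2)]
  thr <- edges[k + 1L]
  varT <- sum(p * (mids - muT)^2)
  attr(thr, "separability") <- if (varT > 0) sB[k] / varT else 0
  thr
}

#' 3D skeletonization by topology-preserving thinning
#'
#' Iterative border peeling with simple-point checks (26-connectivity for
#' the foreground, 6 for the background) until objects are reduced to
#' single-voxel-wide lines; curve endpoints are preserved, so the operation
#' is idempotent.
#'
#' @param mask logical 3D array (or [VolumeImage-class] of 0/1).
#' @return logical array of the same dimensions.
#' @export
skeletonize3D <- function(mask) {
  arr <- if (is(mask, "VolumeImage")) imgData(mask) > 0 else mask
  storage.mode(arr) <- "logical"
  out <- cpp_thin3d(arr, as.integer(dim(arr)))
  dim(out) <- dim(arr)
  out
}

#' Cell and bath masks from the extracellular volume channel
#'
#' The cell is the below-threshold (dye-free) region of the calcein-type
#' channel after morphological closing (to absorb tubule lumina and other
#' artifactual holes) and largest-connected-component selection; the bath is
#' the above-threshold region at least `bathMargin_um` away from the cell.
#'
#' @param volumeChannel [VolumeImage-class].
#' @param psf [PSFSpec-class]; sets the default closing radius (one FWHM,
#'   enough to absorb sub-resolution lumina) and bath margin (2 FWHM).
#' @param closing_um half-width of the (separable box) closing element, um.
#' @param bathMargin_um distance from the cell boundary excluded from the
#'   bath reference region.
#' @return list(cell, bath) of logical arrays.
#' @export
cellMask <- function(volumeChannel, psf, closing_um = NULL,
                     bathMargin_um = NULL) {
  arr <- imgData(volumeChannel)
  vs <- voxelSize(volumeChannel)
  thr <- otsuThreshold(arr)
  below <- arr < thr
  if (!any(below)) stop("no below-threshold region: image appears to be all bath")
  if (is.null(closing_um)) closing_um <- max(psfFWHM(psf))
  dims <- as.integer(dim(arr))
  closed <- boxClose(below, closing_um, vs)
  cell <- cpp_largest_component(closed, dims, 6L)
  dim(cell) <- dim(arr)
  if (is.null(bathMargin_um)) bathMargin_um <- 2 * max(psfFWHM(psf))
  far <- !boxDilate(cell, bathMargin_um, vs)
  bath <- (arr >= thr) & far
  list(cell = cell, bath = bath)
}

# central-difference gradient components in physical units; returns list of
# three arrays (d/dz, d/dy, d/dx)
gradient3d <- function(arr, vs) {
  shift <- function(a, ax, by) {
    n <- dim(a)[ax]
    idx <- pmin(pmax(seq_len(n) + by, 1L), n)
    if (ax == 1) a[idx, , , drop = FALSE]
    else if (ax == 2) a[, idx, , drop = FALSE]
    else a[, , idx, drop = FALSE]
  }
  lapply(1:3, function(ax)
    (shift(arr, ax, 1L) - shift(arr, ax, -1L)) / (2 * vs[ax]))
}

#' Surface-sarcolemma voxel set
#'
#' Refines the cell border to the in-focus, non-z-groove surface: cell-mask
#' boundary voxels are kept where (a) the gradient magnitudes of both
#' channels exceed their Otsu-derived cutoffs (skipped when the gradient
#' distribution is unimodal), (b) the boundary normal lies within
#' `coneDeg` of the lateral (x-y) plane, rejecting the out-of-focus top and
#' bottom caps. Surviving voxels are snapped to the membrane-channel
#' maximum along the surface normal so the set sits on the membrane plane
#' itself, then filtered by membrane strength, by the half-space mid-step
#' criterion on the volume channel, and by local recession (c): a voxel is
#' rejected when any neighbor within `flatnessRadius_um` lies more than
#' `recessionBand_um` further toward the bath along the local normal,
#' which removes z-groove invagination mouths (recessed behind the
#' surrounding crests).
#'
#' @param membraneChannel,volumeChannel [VolumeImage-class]s.
#' @param cell logical cell mask.
#' @param coneDeg half-angle (degrees) of the acceptance cone around the
#'   lateral plane.
#' @param recessionBand_um tolerated recession behind neighboring surface
#'   voxels (um).
#' @param flatnessRadius_um neighborhood radius for the recession test (um).
#' @param refineRange voxels searched along the normal for the membrane peak.
#' @param minMembraneFrac after snapping, voxels whose membrane intensity
#'   falls below this fraction of the median over candidates are rejected
#'   (out-of-focus borders carry weak membrane signal).
#' @param bath optional bath mask used to calibrate the volume-channel step
#'   level.
#' @param volumeWindow the surface reference must sit at the half-space
#'   mid-step of the volume channel, where the 0.5 calibration holds:
#'   voxels whose bath-relative volume signal differs from 0.5 by more
#'   than this are rejected. This removes z-groove mouths, where the
#'   closing-bridged border hangs in dye-filled extracellular space.
#' @return logical array (SS voxel set).
#' @export
surfaceSkeleton <- function(membraneChannel, volumeChannel, cell,
                            coneDeg = 60, recessionBand_um = 0.1,
                            flatnessRadius_um = 0.9, refineRange = 4L,
                            minMembraneFrac = 0.7, bath = NULL,
                            volumeWindow = 0.15) {
  if (is.null(cell) || !any(cell)) stop("cell mask is empty or missing")
  mem <- imgData(membraneChannel)
  vol <- imgData(volumeChannel)
  vs <- voxelSize(membraneChannel)
  dims <- as.integer(dim(mem))
  face <- as.matrix(expand.grid(dz = -1L:1L, dy = -1L:1L, dx = -1L:1L))
  face <- face[rowSums(abs(face)) == 1L, ]
  boundary <- cell & dilateMask(!cell, face)
  bidx <- maskIndices(boundary)
  if (nrow(bidx) == 0) stop("cell mask has no boundary")

  gm <- gradient3d(mem, vs)
  gv <- gradient3d(vol, vs)
  magAt <- function(g, idx) {
    sqrt(g[[1]][idx]^2 + g[[2]][idx]^2 + g[[3]][idx]^2)
  }
  gmag_m <- magAt(gm, bidx)
  gmag_v <- magAt(gv, bidx)
  # Otsu-derived gradient cutoffs, capped at 30% of the strong-gradient
  # level so a near-uniform (fully in-focus) border is never half-rejected
  cutoff <- function(v) {
    if (diff(range(v)) <= 0) return(-Inf)
    min(as.numeric(otsuThreshold(v)), 0.3 * quantile(v, 0.9))
  }
  keep <- gmag_m >= cutoff(gmag_m) & gmag_v >= cutoff(gmag_v)

  # boundary normal from the volume gradient (points toward the bath)
  nrm <- cbind(gv[[1]][bidx], gv[[2]][bidx], gv[[3]][bidx])
  nlen <- sqrt(rowSums(nrm^2))
  ok <- nlen > 0
  elev <- rep(90, nrow(bidx))
  elev[ok] <- asin(pmin(1, abs(nrm[ok, 1]) / nlen[ok])) * 180 / pi
  keep <- keep & elev <= coneDeg

  sel <- bidx[keep, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("no surface-sarcolemma voxels found; relax coneDeg or the flatness cutoff")

  # snap to the membrane-intensity maximum along the dominant normal axis
  nsel <- nrm[keep, , drop = FALSE]
  snapped <- matrix(0L, nrow(sel), 3)
  snapval <- numeric(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    ax <- which.max(abs(nsel[i, ]))
    if (!is.finite(nsel[i, ax]) || nsel[i, ax] == 0) ax <- 2L
    best <- sel[i, ]
    bestv <- mem[matrix(best, 1)]
    for (k in c(-(refineRange:1), 1:refineRange)) {
      p <- sel[i, ]
      p[ax] <- p[ax] + k
      if (p[ax] < 1 || p[ax] > dim(mem)[ax]) next
      v <- mem[matrix(p, 1)]
      if (v > bestv) { bestv <- v; best <- p }
    }
    snapped[i, ] <- best
    snapval[i] <- bestv
  }
  good <- snapval >= minMembraneFrac * median(snapval)
  # the SS reference is only valid where the surface behaves as the
  # half-space calibration assumes: volume signal at the membrane = half
  # the bath level; groove mouths (border hanging in extracellular dye)
  # and out-of-focus caps fall outside the window
  bathLevel <- if (!is.null(bath) && any(bath)) mean(vol[bath]) else
    as.numeric(quantile(vol[!cell], 0.9))
  stepFrac <- vol[snapped] / bathLevel
  good <- good & abs(stepFrac - 0.5) <= volumeWindow

  # groove rejection by recession: an SS voxel must be locally most
  # bathward. A voxel is dropped when any neighbor within
  # flatnessRadius_um sits more than recessionBand_um further toward
  # the bath along the local surface normal -- groove mouths and their
  # flanks are recessed behind the surrounding crests, the true surface
  # plane is not recessed behind anything.
  co <- indexToCoord(snapped, vs)
  nGood <- nsel / pmax(sqrt(rowSums(nsel^2)), 1e-12)  # toward the bath
  gi <- which(good)
  if (length(gi) > 10) {
    bins <- floor(sweep(co, 2, flatnessRadius_um, "/"))
    key <- paste(bins[, 1], bins[, 2], bins[, 3])
    # recession is judged against every snapped candidate, filtered or not:
    # a groove bottom is recessed behind its flanks even when those flanks
    # were themselves rejected
    lookup <- split(seq_len(nrow(co)), key)
    recessed <- vapply(gi, function(i) {
      kb <- bins[i, ]
      nb <- unlist(lookup[paste(rep(kb[1] + (-1:1), times = 9),
                                rep(rep(kb[2] + (-1:1), each = 3), times = 3),
                                rep(kb[3] + (-1:1), each = 9))], use.names = FALSE)
      d2 <- rowSums(sweep(co[nb, , drop = FALSE], 2, co[i, ])^2)
      nb <- nb[d2 <= flatnessRadius_um^2]
      if (length(nb) < 2) return(TRUE)
      rel <- sweep(co[nb, , drop = FALSE], 2, co[i, ])
      max(rel %*% nGood[i, ]) > recessionBand_um
    }, logical(1))
    good[gi] <- !recessed
  }
  if (!any(good))
    stop("no surface-sarcolemma voxels found; relax volumeWindow or the ",
         "flatness cutoff")
  out <- array(FALSE, dim(mem))
  out[snapped[good, , drop = FALSE]] <- TRUE
  out
}

#' T-tubule skeleton
#'
#' Combines the thinned membrane skeleton with the cell mask: skeleton
#' voxels inside the cell eroded by one (symmetrized) PSF FWHM, minus the
#' surface sarcolemma, with short spurs pruned.
#'
#' @param membraneSkeleton logical array from [skeletonize3D()].
#' @param cell logical cell mask.
#' @param ssSkeleton logical SS voxel set.
#' @param psf [PSFSpec-class]; its largest FWHM sets the erosion radius.
#' @param voxelSize voxel sizes (z, y, x) um.
#' @param erosion_um override the erosion radius.
#' @param pruneLen spurs shorter than this many voxels are removed.
#' @return logical array (may be empty).
#' @export
ttSkeleton <- function(membraneSkeleton, cell, ssSkeleton, psf, voxelSize,
                       erosion_um = NULL, pruneLen = 2L) {
  if (is.null(erosion_um)) erosion_um <- max(psfFWHM(psf))
  eroded <- boxErode(cell, erosion_um, voxelSize)
  tt <- membraneSkeleton & eroded & !ssSkeleton
  pruneSpurs(tt, voxelSize, pruneLen)
}

# remove leaf branches shorter than pruneLen voxels, and isolated fragments
# of fewer than pruneLen voxels
pruneSpurs <- function(skel, voxelSize, pruneLen = 2L) {
  if (!any(skel) || pruneLen <= 0) return(skel)
  g <- skeletonGraph(skel, voxelSize)
  if (igraph::vcount(g$graph) == 0) return(skel)
  gg <- g$graph
  repeat {
    deg <- igraph::degree(gg)
    junction <- which(deg >= 3)
    leaves <- which(deg == 1)
    drop <- integer()
    for (lf in leaves) {
      path <- lf
      cur <- lf
      prev <- 0L
      repeat {
        nbs <- as.integer(igraph::neighbors(gg, cur))
        nbs <- setdiff(nbs, prev)
        if (length(nbs) != 1L) break       # junction or other endpoint
        nxt <- nbs[1]
        if (deg[nxt] >= 3) { if (length(path) < pruneLen) drop <- c(drop, path); break }
        prev <- cur; cur <- nxt; path <- c(path, cur)
        if (length(path) >= pruneLen) break
      }
    }
    # isolated small components
    cmp <- igraph::components(gg)
    small <- which(cmp$csize < pruneLen)
    if (length(small)) drop <- c(drop, which(cmp$membership %in% small))
    drop <- unique(drop)
    if (!length(drop)) break
    coords_drop <- g$coords[drop, , drop = FALSE]
    skel[coords_drop] <- FALSE
    g <- skeletonGraph(skel, voxelSize)
    gg <- g$graph
    if (igraph::vcount(gg) == 0) break
    break  # a single pruning pass suffices for the default pruneLen
  }
  skel
}

#' Cytosol mask
#'
#' The cell mask minus the dilated t-tubule skeleton neighborhood (and,
#' when given, the surface-sarcolemma neighborhood, whose membrane signal
#' would otherwise contaminate the background estimate); used as the
#' dye-free reference region for background estimation.
#'
#' @param cell logical cell mask.
#' @param ttSkel logical TT skeleton.
#' @param voxelSize voxel sizes (z, y, x) um.
#' @param dilation_um neighborhood radius removed around the skeletons
#'   (default one symmetrized FWHM via `psf`).
#' @param psf optional [PSFSpec-class] supplying the default radius.
#' @param ssSkel optional logical SS voxel set, excluded like the TT
#'   skeleton.
#' @return logical array.
#' @export
cytosolMask <- function(cell, ttSkel, voxelSize, dilation_um = NULL, psf = NULL,
                        ssSkel = NULL) {
  if (is.null(dilation_um)) {
    if (is.null(psf)) stop("give dilation_um or psf")
    dilation_um <- max(psfFWHM(psf))
  }
  excl <- ttSkel
  if (!is.null(ssSkel)) excl <- excl | ssSkel
  cyto <- cell & !boxDilate(excl, dilation_um, voxelSize)
  if (!any(cyto)) stop("cytosol mask is empty")
  cyto
}

#' Build the full MaskSet for a cell
#'
#' Orchestrates [cellMask()], membrane-channel Otsu masking and
#' [skeletonize3D()], [surfaceSkeleton()], [ttSkeleton()] and
#' [cytosolMask()].
#'
#' All masks and skeletons are derived from PSF-symmetrized copies of the
#' channels (the raw channels are blurred laterally to the axial resolution
#' first), so that mask placement -- in particular the skeleton centerline,
#' which must mark the tubule axis rather than laterally-resolved walls --
#' does not depend on tubule orientation.
#'
#' The membrane (t-tubule) mask threshold is an Otsu threshold computed
#' within the eroded cell interior -- where tubules live and the bright SS
#' plane does not dominate the histogram -- floored at `ttMaskFloorFrac`
#' of the SS membrane signal so that a tubule-free cell yields an empty
#' skeleton rather than a spurious one.
#'
#' @param membraneChannel,volumeChannel raw [VolumeImage-class]s.
#' @param psf raw [PSFSpec-class] of the acquisition.
#' @param ttMaskFloorFrac membrane-mask floor as a fraction of the SS
#'   reference signal.
#' @param ... passed on to [surfaceSkeleton()].
#' @return [MaskSet-class].
#' @export
buildMaskSet <- function(membraneChannel, volumeChannel, psf,
                         ttMaskFloorFrac = 0.2, ...) {
  vs <- voxelSize(membraneChannel)
  if (isSymmetrized(psf)) {
    sym <- psf
    memS <- membraneChannel; volS <- volumeChannel
  } else {
    sym <- symmetrizePSF(psf)
    blur <- symmetrizationBlur(psf)
    memS <- applyBlur(membraneChannel, blur)
    volS <- applyBlur(volumeChannel, blur)
  }
  cm <- cellMask(volS, sym)
  ss <- surfaceSkeleton(memS, volS, cm$cell, bath = cm$bath, ...)
  memArr <- imgData(memS)
  ssPeak <- trimmedMean(memArr[ss], 0.1)
  eroded <- boxErode(cm$cell, max(psfFWHM(sym)), vs)
  thr <- tryCatch(as.numeric(otsuThreshold(memArr, within = eroded)),
                  error = function(e) Inf)
  thr <- max(thr, ttMaskFloorFrac * ssPeak)
  memSkel <- skeletonize3D(memArr >= thr)
  tt <- ttSkeleton(memSkel, cm$cell, ss, sym, vs)
  cyto <- cytosolMask(cm$cell, tt, vs, psf = sym, ssSkel = ss)
  new("MaskSet", cell = cm$cell, cytosol = cyto, bath = cm$bath,
      membraneSkeleton = memSkel, ssSkeleton = ss & !tt,
      ttSkeleton = tt, voxelSize = vs)
}
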