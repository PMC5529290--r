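#' Accessors for TubuleVSA classes
#'
#' @param object a TubuleVSA object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(object) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setMethod("imgData", "VolumeImage", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("voxelSize", "VolumeImage", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "MaskSet", function(object) object@voxelSize)

#' PSF accessors
#'
#' @param object a [PSFSpec-class].
#' @param order "zyx" (internal/array order) or "xyz".
#' @return `psfFWHM`/`psfSigma`: numeric length 3 in micrometres;
#'   `isSymmetrized`: logical.
#' @export
psfFWHM <- function(object, order = c("zyx", "xyz")) {
  order <- match.arg(order)
  f <- object@fwhm
  if (order == "xyz") f <- f[c("x", "y", "z")]
  f
}

#' @rdname psfFWHM
#' @export
psfSigma <- function(object, order = c("zyx", "xyz")) fwhmToSigma(psfFWHM(object, order))

#' @rdname psfFWHM
#' @export
isSymmetrized <- function(object) object@state == "symmetrized"

#' @rdname accessors
#' @export
setGeneric("vsaValues", function(object) standardGeneric("vsaValues"))

#' @rdname accessors
#' @export
setMethod("vsaValues", "VSAMap", function(object) object@vsa)

#' @rdname accessors
#' @export
setGeneric("diameterValues", function(object) standardGeneric("diameterValues"))

#' @rdname accessors
#' @export
setMethod("diameterValues", "VSAMap", function(object) object@diameter)

#' @rdname accessors
#' @export
setGeneric("vsaSummary", function(object) standardGeneric("vsaSummary"))

#' @rdname accessors
#' @export
setMethod("vsaSummary", "VSAMap", function(object) object@summary)

#' @rdname accessors
#' @export
setGeneric("truthTubules", function(object) standardGeneric("truthTubules"))

#' @rdname accessors
#' @export
setMethod("truthTubules", "PhantomTruth", function(object) object@tubules)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage %d x %d x %d (z, y, x), voxel %.3g/%.3g/%.3g um\n",
              d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "PSFSpec", function(object) {
  cat(sprintf("PSFSpec (%s): FWHM z/y/x = %.3f/%.3f/%.3f um\n", object@state,
              object@fwhm[1], object@fwhm[2], object@fwhm[3]))
})

setMethod("show", "MaskSet", function(object) {
  cat("MaskSet:\n")
  for (s in c("cell", "cytosol", "bath", "membraneSkeleton", "ssSkeleton",
              "ttSkeleton"))
    cat(sprintf("  %-17s %d voxels\n", s, sum(slot(object, s))))
})

setMethod("show", "VSAMap", function(object) {
  s <- object@summary
  cat(sprintf(
    "VSAMap: %d skeleton voxels (%d dropped), V:SA %.3f +/- %.3f (SD), D = %.3f um\n",
    s$n, object@dropped, s$mean, s$sd, vsaToDiameter(s$mean, object@fwhm)))
})

setMethod("show", "NetworkStats", function(object) {
  cat(sprintf("NetworkStats: L = %.3f um/um^3; transverse/axial/oblique = %.0f/%.0f/%.0f%%\n",
              object@lengthDensity, object@fractions["transverse"],
              object@fractions["axial"], object@fractions["oblique"]))
  cat(sprintf("  area density %.3g um^2/um^3, volume fraction %.3g%%, membrane fraction %.3g%%\n",
              object@areaDensity, object@volumeFraction, object@membraneFraction))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %d tubules, cell %.1f um^3, TT area %.2f um^2, TT volume %.3f um^3\n",
              nrow(object@tubules), object@cellVolume_um3,
              object@ttMembraneArea_um2, object@ttLuminalVolume_um3))
})
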