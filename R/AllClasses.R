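#' VolumeImage: a 3D intensity grid with physical voxel sizes
#'
#' The common currency of all image operations in the package. The array is
#' stored in (z, y, x) order and all coordinate triples in the package follow
#' that order; voxel centers sit at (index - 0.5) * voxelSize in micrometres
#' (1-based indices).
#'
#' @slot data 3D numeric array, dimensions (nz, ny, nx).
#' @slot voxelSize named numeric of length 3 (z, y, x), micrometres.
#' @export
setClass("VolumeImage",
  representation(data = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (length(object@voxelSize) != 3L) return("voxelSize must have length 3")
    if (any(object@voxelSize <= 0)) return("voxel sizes must be positive")
    TRUE
  })

#' Construct a VolumeImage
#'
#' @param data 3D numeric array in (z, y, x) order.
#' @param voxelSize numeric length 3, voxel size in micrometres (z, y, x).
#' @return A [VolumeImage-class] object.
#' @examples
#' vi <- volumeImage(array(0, c(4, 8, 8)), c(0.18, 0.06, 0.06))
#' voxelSize(vi)
#' @export
volumeImage <- function(data, voxelSize) {
  new("VolumeImage", data = data,
      voxelSize = setNames(as.numeric(voxelSize), c("z", "y", "x")))
}

#' PSFSpec: Gaussian-equivalent microscope resolution
#'
#' Per-axis full width at half maximum of the (Gaussian-equivalent) point
#' spread function, either as measured ("raw") or after the lateral blurring
#' that makes the PSF spherical ("symmetrized").
#'
#' @slot fwhm named numeric length 3 (z, y, x), micrometres.
#' @slot state "raw" or "symmetrized".
#' @export
setClass("PSFSpec",
  representation(fwhm = "numeric", state = "character"),
  validity = function(object) {
    if (length(object@fwhm) != 3L) return("fwhm must have length 3")
    if (any(object@fwhm <= 0)) return("all FWHM must be positive")
    if (!object@state %in% c("raw", "symmetrized"))
      return("state must be 'raw' or 'symmetrized'")
    if (object@state == "symmetrized" &&
        diff(range(object@fwhm)) > 1e-9 * max(object@fwhm))
      return("a symmetrized PSF must be isotropic")
    TRUE
  })

#' Construct a PSFSpec
#'
#' @param fwhm_um FWHM per axis in micrometres. Either a single number
#'   (isotropic), or length 3 in (x, y, z) order -- the order used in the
#'   PSF YAML schema. Internally stored as (z, y, x).
#' @param state "raw" (as measured) or "symmetrized".
#' @return A [PSFSpec-class] object.
#' @examples
#' psfSpec(c(0.25, 0.25, 0.60))
#' @export
psfSpec <- function(fwhm_um, state = "raw") {
  if (length(fwhm_um) == 1L) fwhm_um <- rep(fwhm_um, 3L)
  stopifnot(length(fwhm_um) == 3L)
  new("PSFSpec", fwhm = setNames(as.numeric(fwhm_um[c(3, 2, 1)]), c("z", "y", "x")),
      state = state)
}

#' MaskSet: binary masks and skeletons for one cell
#'
#' Co-registered binary volumes on the input grid: the cell region, the
#' cytosol (cell minus the t-tubule neighborhood), the perfusion bath, the
#' thinned membrane skeleton, the surface-sarcolemma (SS) voxel set, and the
#' t-tubule (TT) skeleton.
#'
#' @slot cell,cytosol,bath,membraneSkeleton,ssSkeleton,ttSkeleton logical
#'   arrays with identical dimensions.
#' @slot voxelSize numeric length 3 (z, y, x), micrometres.
#' @export
setClass("MaskSet",
  representation(cell = "array", cytosol = "array", bath = "array",
                 membraneSkeleton = "array", ssSkeleton = "array",
                 ttSkeleton = "array", voxelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@cell)
    for (s in c("cytosol", "bath", "membraneSkeleton", "ssSkeleton", "ttSkeleton"))
      if (!identical(dim(slot(object, s)), d))
        return(sprintf("mask '%s' dimensions differ from cell mask", s))
    if (any(object@bath & object@cell)) return("bath and cell masks overlap")
    if (any(object@ttSkeleton & !object@cell))
      return("TT skeleton extends outside the cell mask")
    if (any(object@ssSkeleton & object@ttSkeleton))
      return("SS and TT skeletons overlap")
    if (any(object@cytosol & !object@cell))
      return("cytosol extends outside the cell mask")
    TRUE
  })

#' NormalizedPair: background-subtracted, symmetrized, normalized channels
#'
#' The volume channel is normalized so that its mean over the bath mask is 1
#' (a dimensionless extracellular volume fraction); the membrane channel so
#' that its mean over the SS skeleton is 1 (relative surface density).
#'
#' @slot volume,membrane [VolumeImage-class] objects.
#' @slot psf the (symmetrized) [PSFSpec-class] the channels were blurred to.
#' @slot constants list with the normalization constants actually used.
#' @slot provenance list: mask voxel counts, background parameters, etc.
#' @export
setClass("NormalizedPair",
  representation(volume = "VolumeImage", membrane = "VolumeImage",
                 psf = "PSFSpec", constants = "list", provenance = "list"))

#' VSAMap: per-skeleton-voxel V:SA and derived diameters
#'
#' @slot coords integer matrix (n x 3), 1-based (z, y, x) skeleton voxel
#'   indices retained after the membrane-signal floor.
#' @slot vsa numeric, dimensionless V:SA per retained voxel.
#' @slot diameter numeric, derived tubule diameter per voxel (um).
#' @slot fwhm numeric, the symmetrized PSF FWHM used in the conversion (um).
#' @slot summary list: mean, sd, sem, n, histogram.
#' @slot dropped integer, skeleton voxels dropped by the membrane floor.
#' @export
setClass("VSAMap",
  representation(coords = "matrix", vsa = "numeric", diameter = "numeric",
                 fwhm = "numeric", summary = "list", dropped = "integer"),
  validity = function(object) {
    if (length(object@vsa) != nrow(object@coords)) return("vsa/coords length mismatch")
    if (length(object@diameter) != length(object@vsa))
      return("diameter/vsa length mismatch")
    if (any(object@vsa < 0)) return("V:SA must be non-negative")
    TRUE
  })

#' PhantomSpec: scene description for the forward simulator
#'
#' @slot gridDim integer length 3, voxels per axis (z, y, x).
#' @slot voxelSize numeric length 3, micrometres (z, y, x).
#' @slot surfaceAxis which axis the cell surface plane is orthogonal to
#'   ("z", "y" or "x"); the cell occupies the high-coordinate side.
#' @slot surfacePosition plane position along that axis, micrometres.
#' @slot grooveAmplitude,groovePeriod sinusoidal z-groove corrugation of the
#'   surface along the cell long axis (um); amplitude 0 disables.
#' @slot tubules list of tubules; see [straightTubule()].
#' @slot bathAmplitude volume-dye intensity of the bath (arbitrary units).
#' @slot membraneDensity membrane-dye surface density (units per um^2).
#' @slot noise list(type = "none"|"gaussian"|"poisson", sd, scale).
#' @slot seed integer RNG seed for the noise model.
#' @export
setClass("PhantomSpec",
  representation(gridDim = "integer", voxelSize = "numeric",
                 surfaceAxis = "character", surfacePosition = "numeric",
                 grooveAmplitude = "numeric", groovePeriod = "numeric",
                 tubules = "list", bathAmplitude = "numeric",
                 membraneDensity = "numeric", noise = "list", seed = "integer"),
  validity = function(object) {
    if (any(object@voxelSize <= 0)) return("voxel sizes must be positive")
    if (any(object@gridDim < 4L)) return("grid too small")
    if (!object@surfaceAxis %in% c("z", "y", "x")) return("bad surfaceAxis")
    for (tb in object@tubules) {
      if (tb$diameter <= 0) return("tubule diameters must be positive")
      if (tb$ellipticity <= 0 || tb$ellipticity > 1)
        return("ellipticity must be in (0, 1]")
    }
    TRUE
  })

#' PhantomTruth: ground truth of a rendered phantom
#'
#' @slot tubules data.frame with one row per tubule: diameter_um,
#'   ellipticity, orientation_deg (angle from the transverse plane),
#'   length_um, area_um2, volume_um3.
#' @slot cellVolume_um3,ttMembraneArea_um2,ttLuminalVolume_um3 scalars.
#' @export
setClass("PhantomTruth",
  representation(tubules = "data.frame", cellVolume_um3 = "numeric",
                 ttMembraneArea_um2 = "numeric", ttLuminalVolume_um3 = "numeric"),
  validity = function(object) {
    if (object@cellVolume_um3 < 0 || object@ttMembraneArea_um2 < 0 ||
        object@ttLuminalVolume_um3 < 0)
      return("volumes and areas must be non-negative")
    TRUE
  })

#' NetworkStats: t-tubule network organization summary
#'
#' @slot lengthDensity skeleton length per cell volume (um/um^3).
#' @slot fractions named numeric: transverse, axial, oblique (percent of
#'   classified skeleton length; sums to 100).
#' @slot meanDiameter mean tubule diameter (um).
#' @slot areaDensity TT membrane area per cell volume (um^2/um^3).
#' @slot volumeFraction TT volume as percent of cell volume.
#' @slot membraneFraction percent of total cell membrane in TTs (NA when the
#'   total membrane density is not supplied).
#' @export
setClass("NetworkStats",
  representation(lengthDensity = "numeric", fractions = "numeric",
                 meanDiameter = "numeric", areaDensity = "numeric",
                 volumeFraction = "numeric", membraneFraction = "numeric"))
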