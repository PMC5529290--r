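#' Estimate the per-voxel background of a channel
#'
#' Over the cytosol the background is the image itself after a small box
#' median filter; at cell voxels outside the cytosol (the t-tubule skeleton
#' and its neighborhood) it is nearest-neighbor interpolated (Euclidean
#' distance in physical units, ties broken by lowest z, then y, then x
#' index) from the surrounding cytosol; outside the cell it is 0 for the
#' membrane channel and 0 for the volume channel as well -- the bath is
#' signal there and is never background-subtracted.
#'
#' @param image [VolumeImage-class] or array.
#' @param masks [MaskSet-class] (cytosol and cell masks are used).
#' @param medianRadius_vox half-width of the median filter box (voxels).
#' @param voxelSize required when `image` is a bare array.
#' @return background array of the image's dimensions.
#' @export
estimateBackground <- function(image, masks, medianRadius_vox = 2L,
                               voxelSize = NULL) {
  arr <- if (is(image, "VolumeImage")) imgData(image) else image
  vs <- if (is(image, "VolumeImage")) voxelSize(image) else voxelSize
  cyto <- masks@cytosol
  if (!any(cyto)) stop("cytosol mask is empty")
  dims <- as.integer(dim(arr))
  med <- cpp_median_box(as.double(arr), dims,
                        rep(as.integer(medianRadius_vox), 3L), cyto)
  dim(med) <- dim(arr)
  bg <- array(0, dim(arr))
  bg[cyto] <- med[cyto]
  targets <- masks@cell & !cyto
  tidx <- maskIndices(targets)
  if (nrow(tidx)) {
    vals <- cpp_nearest_value(storage.mode2int(tidx - 1L), cyto,
                              as.double(med), dims, as.double(vs))
    bg[tidx] <- vals
  }
  bg
}

#' Subtract a background image
#'
#' Plain elementwise subtraction; negative values are kept (clipping is
#' deferred to the final ratio stage so that the symmetrization blur
#' averages correctly).
#'
#' @param image [VolumeImage-class] or array.
#' @param background array from [estimateBackground()].
#' @return same type as `image`.
#' @export
subtractBackground <- function(image, background) {
  arr <- if (is(image, "VolumeImage")) imgData(image) else image
  if (!identical(dim(arr), dim(background)))
    stop("image and background dimensions differ")
  out <- arr - background
  if (is(image, "VolumeImage")) volumeImage(out, voxelSize(image)) else out
}

#' Normalize the channel pair to physical references
#'
#' The volume channel is divided by the trimmed mean (central 80%) of its
#' bath values, making it a dimensionless extracellular volume fraction
#' (bath = 1); the membrane channel is divided by the trimmed mean over the
#' SS skeleton, making it a relative surface density (SS = 1). Both
#' channels must already be background-subtracted and symmetrized.
#'
#' @param volume,membrane [VolumeImage-class]s (symmetrized).
#' @param masks [MaskSet-class] with non-empty bath mask and SS skeleton.
#' @param psf the symmetrized [PSFSpec-class].
#' @param trim fraction trimmed from each tail of the reference values.
#' @return [NormalizedPair-class].
#' @export
normalizePair <- function(volume, membrane, masks, psf, trim = 0.1) {
  if (!any(masks@bath)) stop("bath mask is empty")
  if (!any(masks@ssSkeleton)) stop("SS skeleton is empty")
  bathRef <- trimmedMean(imgData(volume)[masks@bath], trim)
  ssRef <- trimmedMean(imgData(membrane)[masks@ssSkeleton], trim)
  if (!is.finite(bathRef) || bathRef <= 0)
    stop("bath normalization constant is not positive")
  if (!is.finite(ssRef) || ssRef <= 0)
    stop("SS normalization constant is not positive")
  vn <- volumeImage(imgData(volume) / bathRef, voxelSize(volume))
  mn <- volumeImage(imgData(membrane) / ssRef, voxelSize(membrane))
  new("NormalizedPair", volume = vn, membrane = mn, psf = psf,
      constants = list(bathRef = bathRef, ssRef = ssRef),
      provenance = list(
        bathVoxels = sum(masks@bath), ssVoxels = sum(masks@ssSkeleton),
        ttVoxels = sum(masks@ttSkeleton), trim = trim))
}

#' Background-subtract, symmetrize and normalize a channel pair
#'
#' The fixed processing order of the method: background subtraction, then
#' the lateral blur that renders the PSF spherical, then normalization of
#' the volume channel to the bath and the membrane channel to the SS.
#'
#' @param membrane,volume raw [VolumeImage-class] channels.
#' @param masks [MaskSet-class].
#' @param psf raw [PSFSpec-class] (symmetrization is derived from it); pass
#'   a symmetrized PSFSpec to skip the extra blur.
#' @param medianRadius_vox background median-filter half-width (voxels).
#' @param trim trimmed-mean tail fraction for the normalization references.
#' @return [NormalizedPair-class].
#' @export
preprocessChannels <- function(membrane, volume, masks, psf,
                               medianRadius_vox = 2L, trim = 0.1) {
  bgM <- estimateBackground(membrane, masks, medianRadius_vox)
  bgV <- estimateBackground(volume, masks, medianRadius_vox)
  mem <- subtractBackground(membrane, bgM)
  vol <- subtractBackground(volume, bgV)
  if (!isSymmetrized(psf)) {
    blur <- symmetrizationBlur(psf)
    mem <- applyBlur(mem, blur)
    vol <- applyBlur(vol, blur)
    psf <- symmetrizePSF(psf)
  }
  normalizePair(vol, mem, masks, psf, trim)
}
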