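#' Estimate the PSF from a bead stack
#'
#' Fits a 1D Gaussian along each axis through the bead centroid and corrects
#' the fitted widths for the finite bead size by quadrature subtraction of
#' the sphere's equivalent Gaussian width (a uniform ball of radius R has
#' per-axis variance R^2/5).
#'
#' @param beadStack [VolumeImage-class] containing a single dominant bead.
#' @param beadDiameter_um physical bead diameter (um); 0 for a point source.
#' @return [PSFSpec-class] with state "raw".
#' @export
measurePSF <- function(beadStack, beadDiameter_um = 0.17) {
  arr <- imgData(beadStack)
  vs <- voxelSize(beadStack)
  bg <- median(arr)
  pk <- which.max(arr)
  if (arr[pk] <= bg + 1e-12 * (abs(bg) + 1))
    stop("no peak above background in bead stack")
  pos <- arrayInd(pk, dim(arr))[1, ]
  if (any(pos <= 3) || any(dim(arr) - pos < 3))
    stop("bead too close to stack boundary for a PSF fit")

  fitAxis <- function(ax) {
    idx <- lapply(seq_along(dim(arr)), function(a)
      if (a == ax) seq_len(dim(arr)[a]) else pos[a])
    prof <- as.numeric(do.call(`[`, c(list(arr), idx)))
    t <- (seq_along(prof) - 0.5) * vs[ax]
    w <- pmax(prof - bg, 0)
    mu0 <- sum(t * w) / sum(w)
    s0 <- sqrt(sum((t - mu0)^2 * w) / sum(w))
    fit <- tryCatch(
      nls(prof ~ A * exp(-(t - mu)^2 / (2 * s^2)) + c0,
          start = list(A = max(prof) - bg, mu = mu0, s = s0, c0 = bg),
          control = list(maxiter = 200, warnOnly = FALSE)),
      error = function(e) stop("Gaussian PSF fit did not converge along axis ",
                               c("z", "y", "x")[ax]))
    abs(coef(fit)[["s"]])
  }
  s_fit <- vapply(1:3, fitAxis, numeric(1))
  s_bead2 <- (beadDiameter_um / 2)^2 / 5
  if (any(s_fit^2 <= s_bead2))
    stop("fitted width smaller than the bead itself; cannot deconvolve bead size")
  s_psf <- sqrt(s_fit^2 - s_bead2)
  psfSpec(sigmaToFwhm(s_psf)[c(3, 2, 1)], state = "raw")
}

#' Blur widths that make the PSF spherically symmetric
#'
#' Lateral (x-y) resolution is degraded to match the (worse) axial
#' resolution: extra Gaussian widths sigma_extra = sqrt(sigma_z^2 -
#' sigma_axis^2) per lateral axis, 0 along z. Convolving with these widths
#' makes the effective PSF isotropic with FWHM equal to the raw z FWHM, so
#' that signal intensity no longer depends on tubule orientation.
#'
#' @param raw [PSFSpec-class] with state "raw"; FWHM_z must be the largest.
#' @return named numeric (z, y, x): extra blur sigmas in um.
#' @examples
#' symmetrizationBlur(psfSpec(c(0.25, 0.25, 0.60)))
#' @export
symmetrizationBlur <- function(raw) {
  f <- psfFWHM(raw)
  if (f["z"] < f["x"] - 1e-12 || f["z"] < f["y"] - 1e-12)
    stop("symmetrization assumes z is the lowest-resolution axis; ",
         "got FWHM z < lateral FWHM")
  s <- fwhmToSigma(f)
  setNames(c(0, sqrt(pmax(s["z"]^2 - s[c("y", "x")]^2, 0))), c("z", "y", "x"))
}

#' @rdname symmetrizationBlur
#' @return `symmetrizePSF`: the symmetrized [PSFSpec-class] (isotropic, FWHM
#'   equal to the raw z FWHM).
#' @export
symmetrizePSF <- function(raw) {
  f <- psfFWHM(raw)
  symmetrizationBlur(raw)  # validates the precondition
  psfSpec(rep(f[["z"]], 3), state = "symmetrized")
}

#' Apply a Gaussian blur in physical units
#'
#' Separable convolution with per-axis Gaussian kernels specified by their
#' sigmas in micrometres; the grid is unchanged. Kernels are truncated at 4
#' sigma; boundaries are padded by edge replication so half-space scenes keep
#' their asymptotic values.
#'
#' @param image [VolumeImage-class] or 3D array (then `voxelSize` required).
#' @param blurSigma_um numeric length 3 (z, y, x) or a single number.
#' @param voxelSize voxel sizes (z, y, x) when `image` is a bare array.
#' @return same type as `image`.
#' @export
applyBlur <- function(image, blurSigma_um, voxelSize = NULL) {
  if (is(image, "VolumeImage")) {
    vs <- voxelSize(image); arr <- imgData(image)
  } else {
    vs <- voxelSize; arr <- image
  }
  if (length(blurSigma_um) == 1L) blurSigma_um <- rep(blurSigma_um, 3L)
  s_vox <- blurSigma_um / vs
  if (any(s_vox > 0 & s_vox < 0.5))
    warning("blur sigma under-sampled (< 0.5 voxel) on some axis")
  out <- gaussBlur(arr, blurSigma_um, vs)
  if (is(image, "VolumeImage")) volumeImage(out, vs) else out
}

# measured FWHM of a 1D profile by linear interpolation at half maximum
profileFWHM <- function(prof, pitch) {
  prof <- prof - min(prof)
  pk <- which.max(prof)
  half <- prof[pk] / 2
  left <- right <- NA_real_
  for (i in seq(pk, 2)) {
    if (prof[i - 1] <= half) {
      left <- i - 1 + (half - prof[i - 1]) / (prof[i] - prof[i - 1])
      break
    }
  }
  for (i in seq(pk, length(prof) - 1)) {
    if (prof[i + 1] <= half) {
      right <- i + 1 - (half - prof[i + 1]) / (prof[i] - prof[i + 1])
      break
    }
  }
  (right - left) * pitch
}

# measured FWHM per axis of a point-like object in a 3D array
stackFWHM <- function(arr, vs) {
  pos <- arrayInd(which.max(arr), dim(arr))[1, ]
  vapply(1:3, function(ax) {
    idx <- lapply(seq_along(dim(arr)), function(a)
      if (a == ax) seq_len(dim(arr)[a]) else pos[a])
    profileFWHM(as.numeric(do.call(`[`, c(list(arr), idx))), vs[ax])
  }, numeric(1))
}
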