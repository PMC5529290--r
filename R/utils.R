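#' @useDynLib TubuleVSA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor.test median nls coef quantile rnorm rpois sd setNames
#'   var.test wilcox.test prcomp pnorm
#' @importFrom graphics hist
#' @importFrom utils write.csv
NULL

FWHM_SIGMA <- 2 * sqrt(2 * log(2))

#' Convert Gaussian FWHM to standard deviation (and back)
#'
#' The fixed conversion \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})} used throughout
#' the package.
#'
#' @param fwhm,sigma numeric, in any consistent length unit.
#' @return numeric of the same length.
#' @export
fwhmToSigma <- function(fwhm) fwhm / FWHM_SIGMA

#' @rdname fwhmToSigma
#' @export
sigmaToFwhm <- function(sigma) sigma * FWHM_SIGMA

# Normalized Gaussian kernel at voxel pitch, truncated at 4 sigma.
# Taps are bin-integrated (pnorm differences), which makes the discrete
# convolution exact for piecewise-constant (voxel box-integrated) fields --
# point-sampled taps misquote such fields by several percent once the
# pitch approaches sigma, as it does along z.
gaussKernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half, half)
  k <- pnorm(x + 0.5, sd = sigma_vox) - pnorm(x - 0.5, sd = sigma_vox)
  k / sum(k)
}

# Separable Gaussian blur of a (z, y, x) array; sigma_um per axis (z, y, x).
gaussBlur <- function(arr, sigma_um, voxelSize) {
  dims <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    s_vox <- sigma_um[ax] / voxelSize[ax]
    if (s_vox <= 0) next
    out <- cpp_conv_axis(as.double(out), as.integer(dims),
                         gaussKernel(s_vox), ax - 1L)
  }
  dim(out) <- dims
  out
}

# Integer (dz, dy, dx) offsets of an ellipsoid of physical radius r_um.
ballOffsets <- function(r_um, voxelSize) {
  n <- pmax(0L, floor(r_um / voxelSize))
  g <- expand.grid(dz = -n[1]:n[1], dy = -n[2]:n[2], dx = -n[3]:n[3])
  d2 <- (g$dz * voxelSize[1])^2 + (g$dy * voxelSize[2])^2 + (g$dx * voxelSize[3])^2
  as.matrix(g[d2 <= r_um^2 + 1e-12, , drop = FALSE])
}

dilateMask <- function(mask, offsets) {
  out <- cpp_morph(as.logical(mask), as.integer(dim(mask)),
                   storage.mode2int(offsets), TRUE)
  dim(out) <- dim(mask); out
}

erodeMask <- function(mask, offsets) {
  out <- cpp_morph(as.logical(mask), as.integer(dim(mask)),
                   storage.mode2int(offsets), FALSE)
  dim(out) <- dim(mask); out
}

# box-average downsample by integer factors per axis (z, y, x)
boxDownsample <- function(arr, r) {
  d <- dim(arr)
  stopifnot(all(d %% r == 0))
  if (r[1] > 1) {
    arr <- colMeans(array(arr, c(r[1], d[1] / r[1], d[2], d[3])))
    d <- dim(arr)
  }
  if (r[2] > 1) {
    arr <- aperm(colMeans(array(aperm(arr, c(2, 1, 3)),
                                c(r[2], d[2] / r[2], d[1], d[3]))), c(2, 1, 3))
    d <- dim(arr)
  }
  if (r[3] > 1) {
    arr <- aperm(colMeans(array(aperm(arr, c(3, 1, 2)),
                                c(r[3], d[3] / r[3], d[1], d[2]))), c(2, 3, 1))
  }
  arr
}

# separable box morphology with per-axis half-widths given in physical units
boxMorph <- function(mask, r_um, voxelSize, dilate) {
  hw <- pmax(0L, floor(r_um / voxelSize + 1e-9))
  out <- as.logical(mask)
  dims <- as.integer(dim(mask))
  for (ax in 1:3) {
    if (hw[ax] <= 0L) next
    out <- cpp_box_morph_axis(out, dims, as.integer(hw[ax]), ax - 1L, dilate)
  }
  dim(out) <- dim(mask)
  out
}

boxDilate <- function(mask, r_um, voxelSize) boxMorph(mask, r_um, voxelSize, TRUE)
boxErode <- function(mask, r_um, voxelSize) boxMorph(mask, r_um, voxelSize, FALSE)
boxClose <- function(mask, r_um, voxelSize)
  boxErode(boxDilate(mask, r_um, voxelSize), r_um, voxelSize)

storage.mode2int <- function(m) {
  m <- as.matrix(m); storage.mode(m) <- "integer"; m
}

# voxel center coordinates (um) for 1-based array indices, order (z, y, x)
indexToCoord <- function(idx, voxelSize) {
  sweep(idx - 0.5, 2, voxelSize, "*")
}

# trimmed mean keeping the central (1 - 2*trim) of the distribution
trimmedMean <- function(x, trim = 0.1) mean(x, trim = trim)

# mask as 1-based (z, y, x) index matrix
maskIndices <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# deterministic local RNG scope
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}
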