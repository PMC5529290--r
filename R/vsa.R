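#' Convert V:SA to tubule diameter (cylindrical model)
#'
#' For a sub-resolution cylindrical tubule imaged with a spherical Gaussian
#' PSF, the bath- and SS-normalized channel ratio at the tubule axis is
#' \deqn{V\!:\!SA = \frac{D}{2\,FWHM}\sqrt{\ln 2 / \pi},}
#' so diameter is linear in V:SA:
#' \eqn{D = 2\,FWHM \cdot V\!:\!SA / \sqrt{\ln 2/\pi}}.
#'
#' @param vsa dimensionless V:SA value(s), >= 0.
#' @param fwhm FWHM of the symmetrized PSF (um), > 0.
#' @return diameter(s) in um.
#' @examples
#' vsaToDiameter(0.139, 0.6015)  # ~0.356 um
#' @export
vsaToDiameter <- function(vsa, fwhm) {
  if (any(fwhm <= 0)) stop("FWHM must be positive")
  if (any(vsa < 0)) stop("V:SA must be non-negative")
  2 * fwhm * vsa / sqrt(log(2) / pi)
}

#' @rdname vsaToDiameter
#' @param diameter tubule diameter (um).
#' @export
diameterToVSA <- function(diameter, fwhm) diameter * modelSlope(fwhm)

#' Model slope of V:SA versus diameter
#'
#' d(V:SA)/dD = sqrt(ln 2 / pi) / (2 FWHM) for the cylindrical model.
#'
#' @param fwhm symmetrized PSF FWHM (um).
#' @return slope in 1/um.
#' @examples
#' modelSlope(0.6015)  # ~0.39
#' @export
modelSlope <- function(fwhm) {
  if (any(fwhm <= 0)) stop("FWHM must be positive")
  sqrt(log(2) / pi) / (2 * fwhm)
}

#' Compute the V:SA map on the t-tubule skeleton
#'
#' The ratio of the normalized volume channel to the normalized membrane
#' channel, evaluated only at TT-skeleton voxels. Voxels whose membrane
#' signal falls below `floorFrac` of the SS reference (i.e. below
#' `floorFrac` after normalization) are dropped and counted, guarding
#' against division blow-up. Negative volume values are clipped to 0 at
#' this (final) stage.
#'
#' @param pair [NormalizedPair-class].
#' @param ttSkel logical TT-skeleton array (e.g. `masks@ttSkeleton`).
#' @param floorFrac membrane-signal floor as a fraction of the SS reference.
#' @param binWidth histogram bin width in V:SA units.
#' @return [VSAMap-class].
#' @export
computeVSA <- function(pair, ttSkel, floorFrac = 0.1, binWidth = 0.01) {
  idx <- maskIndices(ttSkel)
  if (nrow(idx) == 0) stop("TT skeleton is empty")
  vol <- imgData(pair@volume)[idx]
  mem <- imgData(pair@membrane)[idx]
  keep <- mem > floorFrac
  dropped <- sum(!keep)
  if (!any(keep)) stop("all skeleton voxels fall below the membrane floor")
  vsa <- pmax(vol[keep], 0) / mem[keep]
  fwhm <- psfFWHM(pair@psf)[["z"]]
  dia <- vsaToDiameter(vsa, fwhm)
  new("VSAMap", coords = idx[keep, , drop = FALSE], vsa = vsa, diameter = dia,
      fwhm = fwhm, summary = summarizeCell(vsa, binWidth = binWidth),
      dropped = as.integer(dropped))
}

#' Summary statistics and histogram of a V:SA distribution
#'
#' @param x a [VSAMap-class] or a numeric vector of V:SA values.
#' @param binWidth histogram bin width (V:SA units).
#' @return list(mean, sd, sem, n, histogram = data.frame(mid, count)).
#' @export
summarizeCell <- function(x, binWidth = 0.01) {
  v <- if (is(x, "VSAMap")) x@vsa else as.numeric(x)
  if (!length(v)) stop("empty V:SA set")
  breaks <- seq(0, max(v) + binWidth, by = binWidth)
  h <- hist(v, breaks = breaks, plot = FALSE)
  list(mean = mean(v), sd = sd(v), sem = sd(v) / sqrt(length(v)),
       n = length(v),
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Elliptical cross-section equivalent to a circular-model diameter
#'
#' Finds the ellipse with minor/major ratio E whose area-to-perimeter ratio
#' equals that of a circle of the given diameter (A/P = D/4), i.e. the
#' elliptical tubule that would produce the same V:SA. The perimeter uses
#' the complete elliptic integral of the second kind; since A/P is linear
#' in the scale of the ellipse the match is closed-form and exact.
#'
#' @param ellipticity E = minor/major in (0, 1].
#' @param diameter circular-model diameter (um); alternatively give `vsa`
#'   and `fwhm`.
#' @param vsa,fwhm optional route via [vsaToDiameter()].
#' @return named numeric: major and minor full axes (um).
#' @examples
#' ellipseEquivalentAxes(0.75, diameter = 0.356)  # ~0.417 / 0.313 um
#' @export
ellipseEquivalentAxes <- function(ellipticity, diameter = NULL,
                                  vsa = NULL, fwhm = NULL) {
  if (ellipticity <= 0 || ellipticity > 1)
    stop("ellipticity must be in (0, 1]")
  if (is.null(diameter)) diameter <- vsaToDiameter(vsa, fwhm)
  if (ellipticity == 1)
    return(c(major = diameter, minor = diameter))
  m <- 1 - ellipticity^2
  Eint <- pracma::ellipke(m)$e
  a <- diameter * Eint / (pi * ellipticity)
  c(major = 2 * a, minor = 2 * a * ellipticity)
}

#' Integrated V:SA of a tubule neighborhood
#'
#' Instead of sampling the channel ratio at skeleton voxels (which, for a
#' blurred cylinder, saturates above the linear model as the diameter
#' approaches the PSF FWHM), this estimator integrates both normalized
#' channels over the full blurred neighborhood of the skeleton. Because
#' convolution conserves mass, the integrated ratio is exactly linear in
#' diameter for a cylinder of any size: sum(volume)/sum(membrane) =
#' A / (P sigma sqrt(2 pi)) = (D/4) / (sigma sqrt(2 pi)), the same
#' relation inverted by [vsaToDiameter()]. The price is spatial
#' resolution: the window mixes neighboring tubules, so this is most
#' useful for sparse networks and validation scenes.
#'
#' @param pair [NormalizedPair-class].
#' @param ttSkel logical TT-skeleton array.
#' @param radius_um half-width of the integration window around the
#'   skeleton (um); should cover ~3 PSF sigmas.
#' @return a single V:SA value (dimensionless).
#' @export
integratedVSA <- function(pair, ttSkel, radius_um = 0.75) {
  if (!any(ttSkel)) stop("TT skeleton is empty")
  vs <- voxelSize(pair@volume)
  win <- boxDilate(ttSkel, radius_um, vs)
  v <- sum(pmax(imgData(pair@volume)[win], 0))
  m <- sum(imgData(pair@membrane)[win])
  if (m <= 0) stop("no membrane signal in the integration window")
  # voxel volumes cancel; the SS normalization already carries the
  # sigma sqrt(2 pi) line-spread factor, so v/m = (D/4)/(sigma sqrt(2 pi))
  v / m
}

#' Spearman correlation of the two channels over the TT skeleton
#'
#' @param pair [NormalizedPair-class].
#' @param ttSkel logical TT-skeleton array.
#' @return list(rho, p).
#' @export
channelCorrelation <- function(pair, ttSkel) {
  idx <- maskIndices(ttSkel)
  if (nrow(idx) < 10) stop("need at least 10 skeleton voxels")
  a <- imgData(pair@volume)[idx]
  b <- imgData(pair@membrane)[idx]
  if (diff(range(a)) == 0 || diff(range(b)) == 0)
    stop("constant channel values on the skeleton")
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
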