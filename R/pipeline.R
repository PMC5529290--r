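#' Assemble a pipeline run configuration
#'
#' Every tunable parameter of the pipeline lives here with its documented
#' default, so a config (plus the input data and seed) fully determines the
#' output. The config round-trips losslessly through YAML via
#' [writeRunConfig()] / [readRunConfig()].
#'
#' @param membranePath,volumePath input TIFF stacks (multi-page, z slices);
#'   NULL when a phantom is rendered instead.
#' @param voxelSize_um voxel sizes (z, y, x) um for TIFF input.
#' @param psf a [PSFSpec-class], a path to a PSF YAML, or NULL when a bead
#'   stack is given.
#' @param beadPath,beadDiameter_um bead-stack route to the PSF.
#' @param phantom optional [PhantomSpec-class]: render instead of reading.
#' @param floorFrac,binWidth,medianRadius_vox,trim,coneDeg,
#'   recessionBand_um,orientationRadius_um pipeline parameters (see the
#'   stage functions).
#' @param longAxis cell long axis (z, y, x); PCA of the cell mask if NULL.
#' @param totalMembraneDensity_um2um3 optional literature value for the
#'   membrane-fraction estimate.
#' @param outDir optional output directory.
#' @param seed integer seed (phantom noise).
#' @return a named list of class `tvsa_config`.
#' @export
runConfig <- function(membranePath = NULL, volumePath = NULL,
                      voxelSize_um = c(0.18, 0.06, 0.06),
                      psf = NULL, beadPath = NULL, beadDiameter_um = 0.17,
                      phantom = NULL,
                      floorFrac = 0.1, binWidth = 0.01,
                      medianRadius_vox = 2L, trim = 0.1,
                      coneDeg = 60, recessionBand_um = 0.1,
                      orientationRadius_um = 0.5, longAxis = NULL,
                      totalMembraneDensity_um2um3 = NULL,
                      outDir = NULL, seed = 1L) {
  cfg <- list(membranePath = membranePath, volumePath = volumePath,
              voxelSize_um = voxelSize_um, psf = psf, beadPath = beadPath,
              beadDiameter_um = beadDiameter_um, phantom = phantom,
              floorFrac = floorFrac, binWidth = binWidth,
              medianRadius_vox = medianRadius_vox, trim = trim,
              coneDeg = coneDeg, recessionBand_um = recessionBand_um,
              orientationRadius_um = orientationRadius_um,
              longAxis = longAxis,
              totalMembraneDensity_um2um3 = totalMembraneDensity_um2um3,
              outDir = outDir, seed = as.integer(seed))
  class(cfg) <- c("tvsa_config", "list")
  cfg
}

stageCall <- function(name, hint, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s (%s)", name, conditionMessage(e), hint),
         call. = FALSE))
}

#' Run the full V:SA pipeline on one cell
#'
#' Input (rendered phantom or TIFF pair) -> PSF -> masks/skeletons ->
#' background subtraction -> PSF symmetrization -> normalization -> V:SA map
#' and diameters -> network geometry. Deterministic given config + seed.
#'
#' @param config from [runConfig()].
#' @return a `CellReport` list: vsa summary, map, network stats, masksets,
#'   provenance (normalization constants, dropped voxels, config).
#' @export
runPipeline <- function(config) {
  if (!is.null(config$phantom)) {
    psf <- resolvePSF(config)
    rend <- stageCall("phantom", "check the PhantomSpec",
                      renderPhantom(config$phantom, psf))
    membrane <- rend$membrane; volume <- rend$volume
    truth <- rend$truth
  } else {
    truth <- NULL
    psf <- resolvePSF(config)
    membrane <- stageCall("input", "membrane TIFF unreadable",
                          readVolumeTIFF(config$membranePath, config$voxelSize_um))
    volume <- stageCall("input", "volume TIFF unreadable",
                        readVolumeTIFF(config$volumePath, config$voxelSize_um))
  }
  if (!identical(dim(imgData(membrane)), dim(imgData(volume))))
    stop(sprintf("channel shapes differ: membrane %s vs volume %s",
                 paste(dim(imgData(membrane)), collapse = "x"),
                 paste(dim(imgData(volume)), collapse = "x")))

  masks <- stageCall("segmentation", "check thresholds/masks",
                     buildMaskSet(membrane, volume, psf,
                                  coneDeg = config$coneDeg,
                                  recessionBand_um = config$recessionBand_um))
  pair <- stageCall("preprocess", "check bath/SS regions",
                    preprocessChannels(membrane, volume, masks, psf,
                                       medianRadius_vox = config$medianRadius_vox,
                                       trim = config$trim))
  vmap <- stageCall("vsa", "TT skeleton may be empty",
                    computeVSA(pair, masks@ttSkeleton,
                               floorFrac = config$floorFrac,
                               binWidth = config$binWidth))
  meanD <- mean(diameterValues(vmap))
  net <- stageCall("network", "orientation/length estimation failed",
                   networkStats(masks@ttSkeleton, masks@cell,
                                voxelSize(membrane), meanD,
                                longAxis = config$longAxis,
                                totalMembraneDensity_um2um3 =
                                  config$totalMembraneDensity_um2um3,
                                radius_um = config$orientationRadius_um))
  report <- list(
    schema = "tvsa-report-1",
    vsa = vsaSummary(vmap),
    meanDiameter_um = meanD,
    fwhm_um = vmap@fwhm,
    network = list(lengthDensity_um_per_um3 = net@lengthDensity,
                   fractions_pct = as.list(net@fractions),
                   areaDensity_um2um3 = net@areaDensity,
                   volumeFraction_pct = net@volumeFraction,
                   membraneFraction_pct = net@membraneFraction),
    provenance = list(
      constants = pair@constants,
      droppedVoxels = vmap@dropped,
      maskVoxels = list(cell = sum(masks@cell), bath = sum(masks@bath),
                        cytosol = sum(masks@cytosol),
                        ss = sum(masks@ssSkeleton),
                        tt = sum(masks@ttSkeleton)),
      seed = config$seed),
    map = vmap, masks = masks, truth = truth)
  if (!is.null(config$outDir)) writeCellReport(report, config$outDir)
  report
}

resolvePSF <- function(config) {
  p <- config$psf
  if (is(p, "PSFSpec")) return(p)
  if (is.character(p)) return(readPSF(p))
  if (!is.null(config$beadPath)) {
    bead <- readVolumeTIFF(config$beadPath, config$voxelSize_um)
    return(measurePSF(bead, config$beadDiameter_um))
  }
  stop("no PSF source: give psf (spec or YAML path) or beadPath")
}

#' Compare per-cell V:SA means between two groups
#'
#' Mann-Whitney (Wilcoxon rank-sum) test, exact for group sizes up to 8
#' (without ties) and normal approximation with tie correction otherwise,
#' plus a variance-ratio F test and group means with SEM.
#'
#' @param groupA,groupB numeric vectors of per-cell mean V:SA (>= 3 cells
#'   each).
#' @return list(U, p_mannwhitney, F, p_variance, means, sems, n).
#' @export
compareGroups <- function(groupA, groupB) {
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("need at least 3 cells per group")
  exact <- max(length(groupA), length(groupB)) <= 8 &&
    !any(duplicated(c(groupA, groupB)))
  wt <- suppressWarnings(wilcox.test(groupA, groupB, exact = exact,
                                     correct = TRUE))
  ft <- var.test(groupA, groupB)
  list(U = unname(wt$statistic), p_mannwhitney = wt$p.value,
       F = unname(ft$statistic), p_variance = ft$p.value,
       means = c(A = mean(groupA), B = mean(groupB)),
       sems = c(A = sd(groupA) / sqrt(length(groupA)),
                B = sd(groupB) / sqrt(length(groupB))),
       n = c(A = length(groupA), B = length(groupB)))
}

# ---- I/O -----------------------------------------------------------------

#' Read / write 3D stacks as multi-page TIFF
#'
#' Stacks are stored one z-slice per page, rows = y, columns = x, 32-bit
#' float; voxel sizes travel in a YAML sidecar (`<file>.yaml`) written next
#' to the TIFF.
#'
#' @param image [VolumeImage-class].
#' @param path TIFF file path.
#' @param voxelSize_um used when no sidecar is present.
#' @return `readVolumeTIFF`: a [VolumeImage-class].
#' @export
writeVolumeTIFF <- function(image, path) {
  arr <- imgData(image)
  # the tiff writer stores [0, 1]; rescale and record the affine transform
  # in the sidecar so intensities round-trip
  offset <- min(0, min(arr))
  scale <- max(arr - offset)
  if (scale <= 0) scale <- 1
  arr <- (arr - offset) / scale
  slices <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ])
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(
    voxel_size_um = as.list(setNames(
      as.numeric(voxelSize(image)[c("x", "y", "z")]), c("x", "y", "z"))),
    intensity_offset = offset, intensity_scale = scale),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeVolumeTIFF
#' @export
readVolumeTIFF <- function(path, voxelSize_um = c(0.18, 0.06, 0.06)) {
  sidecar <- paste0(path, ".yaml")
  offset <- 0; scale <- 1
  if (file.exists(sidecar)) {
    sc <- yaml::read_yaml(sidecar)
    v <- sc$voxel_size_um
    voxelSize_um <- c(v$z, v$y, v$x)
    offset <- sc$intensity_offset %||% 0
    scale <- sc$intensity_scale %||% 1
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  volumeImage(arr * scale + offset, voxelSize_um)
}

#' Read / write a PSF YAML
#'
#' Schema: `{fwhm_um: [x, y, z], state: raw|symmetrized}`.
#'
#' @param psf [PSFSpec-class].
#' @param path YAML file path.
#' @export
writePSF <- function(psf, path) {
  yaml::write_yaml(list(fwhm_um = as.numeric(psfFWHM(psf, "xyz")),
                        state = psf@state), path)
  invisible(path)
}

#' @rdname writePSF
#' @export
readPSF <- function(path) {
  y <- yaml::read_yaml(path)
  psfSpec(as.numeric(y$fwhm_um), state = y$state %||% "raw")
}

#' Serialize a run configuration to YAML (and back)
#'
#' @param config from [runConfig()]; PhantomSpec/PSFSpec entries are
#'   expanded to plain lists.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  cfg <- unclass(config)
  if (is(cfg$psf, "PSFSpec"))
    cfg$psf <- list(fwhm_um = as.numeric(psfFWHM(cfg$psf, "xyz")),
                    state = cfg$psf@state)
  if (is(cfg$phantom, "PhantomSpec")) {
    sp <- cfg$phantom
    cfg$phantom <- list(
      gridDim = as.integer(sp@gridDim), voxelSize = as.numeric(sp@voxelSize),
      surfaceAxis = sp@surfaceAxis, surfacePosition = sp@surfacePosition,
      grooveAmplitude = sp@grooveAmplitude, groovePeriod = sp@groovePeriod,
      bathAmplitude = sp@bathAmplitude, membraneDensity = sp@membraneDensity,
      noise = sp@noise, seed = sp@seed,
      tubules = lapply(sp@tubules, function(tb) list(
        centerline = as.numeric(t(tb$centerline)), diameter = tb$diameter,
        ellipticity = tb$ellipticity, majorAxis = tb$majorAxis)))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$psf) && is.list(y$psf))
    y$psf <- psfSpec(as.numeric(y$psf$fwhm_um), state = y$psf$state %||% "raw")
  if (!is.null(y$phantom)) {
    ph <- y$phantom
    y$phantom <- phantomSpec(
      gridDim = as.integer(ph$gridDim), voxelSize = as.numeric(ph$voxelSize),
      surfaceAxis = ph$surfaceAxis, surfacePosition = ph$surfacePosition,
      grooveAmplitude = ph$grooveAmplitude, groovePeriod = ph$groovePeriod,
      bathAmplitude = ph$bathAmplitude, membraneDensity = ph$membraneDensity,
      noise = ph$noise, seed = ph$seed,
      tubules = lapply(ph$tubules, function(tb) straightTubule(
        centerline = matrix(as.numeric(tb$centerline), ncol = 3, byrow = TRUE),
        diameter = tb$diameter, ellipticity = tb$ellipticity,
        majorAxis = as.numeric(tb$majorAxis))))
  }
  do.call(runConfig, y[setdiff(names(y), character())])
}

#' Write a CellReport to disk
#'
#' JSON report (without the bulky map/mask members), a CSV of the V:SA map
#' (voxel coordinates, V:SA, diameter), and a CSV of the TT skeleton.
#'
#' @param report from [runPipeline()].
#' @param dir output directory (created if needed).
#' @export
writeCellReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report[setdiff(names(report), c("map", "masks", "truth"))]
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", null = "null")
  map <- report$map
  write.csv(data.frame(z = map@coords[, 1], y = map@coords[, 2],
                       x = map@coords[, 3], vsa = map@vsa,
                       diameter_um = map@diameter),
            file.path(dir, "vsa_map.csv"), row.names = FALSE)
  writeSkeletonCSV(report$masks@ttSkeleton, file.path(dir, "tt_skeleton.csv"))
  invisible(dir)
}

#' Write a skeleton voxel list as CSV
#'
#' Columns z, y, x (1-based indices) and a branch-point flag (voxel has
#' three or more skeleton neighbors).
#'
#' @param skel logical skeleton array.
#' @param path CSV path.
#' @export
writeSkeletonCSV <- function(skel, path) {
  idx <- maskIndices(skel)
  nb <- cpp_neighbor_count26(as.logical(skel), as.integer(dim(skel)))
  dim(nb) <- dim(skel)
  write.csv(data.frame(z = idx[, 1], y = idx[, 2], x = idx[, 3],
                       branch = nb[idx] >= 3L),
            path, row.names = FALSE)
  invisible(path)
}

#' Write phantom outputs (channels, truth, spec)
#'
#' @param rendered list from [renderPhantom()].
#' @param dir output directory.
#' @export
writePhantom <- function(rendered, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVolumeTIFF(rendered$membrane, file.path(dir, "membrane.tif"))
  writeVolumeTIFF(rendered$volume, file.path(dir, "volume.tif"))
  tr <- rendered$truth
  jsonlite::write_json(list(
    tubules = tr@tubules, cellVolume_um3 = tr@cellVolume_um3,
    ttMembraneArea_um2 = tr@ttMembraneArea_um2,
    ttLuminalVolume_um3 = tr@ttLuminalVolume_um3),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}
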