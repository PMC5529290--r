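Package: TubuleVSA
Title: Sub-Diffraction Tubule Diameter from Dual-Dye Volume-to-Surface-Area Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the diameter of transverse-axial tubules (t-tubules) of
    cardiac myocytes below the optical diffraction limit from co-registered 3D
    confocal stacks of a membrane dye (e.g. FM4-64) and an extracellular volume
    dye (e.g. calcein). The ratio of bath-normalized luminal volume signal to
    surface-sarcolemma-normalized membrane signal (V:SA) at the tubule skeleton
    is linear in tubule diameter for a fixed cross-sectional shape, which
    calibrates intensity to physical size. Includes PSF estimation from bead
    stacks and symmetrization blurring, 3D mask/skeleton segmentation,
    background subtraction and physical normalization, tubule network geometry
    (length density, orientation classes, membrane/volume fractions),
    cable-theory space constants, and a forward phantom simulator used to
    validate the whole pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    pracma,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
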