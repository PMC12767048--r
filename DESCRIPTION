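Package: VasculoMap
Title: Quantification of Cerebrovascular Structure and Function from
    Ultrasound Localization Microscopy Exports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-acquisition quantification of cerebrovascular structure and
    function from super-resolution ultrasound localization microscopy (ULM)
    and functional ultrasound (fUS) image products. Computes regional vascular
    coverage from binarized density maps, per-pixel vessel diameter by the
    model-independent local-thickness transform (with a brute-force
    inscribed-circle oracle), blood velocity decoding, Poiseuille-derived
    resting cerebral blood flow maps, the cortical arteriole-to-venule ratio,
    and stimulus-locked neurovascular-coupling metrics, together with the
    two-group statistical layer (Student and Welch t-tests). A synthetic
    vascular phantom generator emulates the scanner exports with known ground
    truth so every stage is verifiable by recovery, including young-versus-aged
    cohort contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    tiff,
    png,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'avr.R'
    'density.R'
    'flow.R'
    'nvc.R'
    'phantom.R'
    'pipeline.R'
    'raster-io.R'
    'stats.R'
    'thickness.R'
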