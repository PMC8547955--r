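Package: follicleMech
Title: Mechanics and Myosin Dynamics of Drosophila Border Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of follicle mechanics during Drosophila
    border cell migration: depth-windowed Hertz (Sneddon cone) fitting of AFM
    nanoindentation force curves to extract basement-membrane and nurse-cell
    Young's moduli, fluorescence-intensity quantification of active Myosin
    regulatory light chain (pMRLC) in fixed follicle images, detection and
    lifetime tracking of transient Myosin puncta in time-lapse movies, and the
    migration-index statistic for border cell cluster position. A synthetic-data
    module generates two-layer indentation curves, follicle image scenes,
    puncta movies and geometry tables with known ground truth so that every
    stage of the pipeline is validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Software
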