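Package: mitoquant
Title: Quantification Pipelines for Mitochondrial Bioenergetics, Morphometry,
    and Autophagy-Flux Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantification
    procedures used in cell-based studies of mitochondrial dynamics and
    autophagy: extracellular-flux (Seahorse-style) ATP production rate
    partitioning into oxidative and glycolytic components, spare respiratory
    capacity, mitochondrial shape morphometry (roundness, aspect ratio) from
    fluorescence images, tandem mRFP-GFP-LC3 autophagosome/autolysosome
    vesicle classification and puncta counting, positive-control-thresholded
    cytometry gating, plate-reader and densitometry ratio normalization, and
    a one-way ANOVA with Newman-Keuls post-hoc statistics layer. A seeded
    synthetic-data generator emulates all the raw input families (flux
    plates, microscopy images, cytometry event sets, plate and densitometry
    tables) with known ground truth for validation and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
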