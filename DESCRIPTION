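Package: wormid
Title: Automated Neuron Identity Annotation for Multi-Cell C. elegans
    Fluorescence Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Assigns neuron identities to cells segmented from two-channel
    3D fluorescence image stacks of the C. elegans head. Detects nuclei by
    local-maxima seeding and Gaussian-mixture refinement, estimates the
    worm's anterior-posterior / left-right / dorsal-ventral body axes by
    principal component analysis with autofluorescence-landmark and
    bilateral-symmetry corrections, extracts pairwise positional features,
    and labels cells by maximum a posteriori inference in a conditional
    random field against a data-driven probabilistic positional atlas.
    Includes atlas construction from multi-annotator datasets,
    leave-one-out accuracy evaluation against consensus labels, per-neuron
    reporter-gene expression quantification, and a synthetic-worm
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
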