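Package: smsepi
Title: Vendor-Neutral SMS-EPI Protocol Generation, Simulation,
    Reconstruction and Quality Assurance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and validating a harmonized simultaneous
    multislice (SMS) echo-planar fMRI protocol end to end: a block/event
    pulse-sequence data model with hardware-limit validation and Pulseq-style
    .seq text file input/output, Shinnar-Le Roux and multiband RF pulse
    design with a Bloch-simulation oracle, design-phase safety estimation
    (peripheral nerve stimulation convolution models and relative RF energy),
    a multi-coil k-space acquisition simulator with digital phantoms, a
    harmonized image reconstruction chain (EPI phase correction, ramp-sampling
    regridding, slice-GRAPPA and SENSE unaliasing, zero-filled partial
    Fourier), and the fBIRN/ABCD phantom quality-assurance metric battery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
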