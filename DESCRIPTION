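Package: ssos
Title: Single-Shot Optical Sectioning for Structured Illumination Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of missing-cone axial frequency information from a
    single pair of pi-phase-shifted, polarization-coded structured-illumination
    images (single-shot optical sectioning, ssOS). Provides a scalar
    pupil-integral widefield PSF/OTF model, a forward imaging simulator with
    fluorescence-anisotropy pattern multiplexing and Poisson noise, the
    non-iterative frequency-space reconstruction (Wiener or Richardson-Lucy
    deconvolution, spectral subtraction, cone recovery and recombination), the
    three-phase homodyne OS-SIM baseline, emulation of ssOS raw pairs from
    conventional three-phase SIM stacks, and evaluation tools (depth-resolved
    modulation profiles on a tilted frequency-chirp phantom and photon-budget
    noise sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
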