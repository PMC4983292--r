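Package: fidproc
Title: Scriptable Processing of Multidimensional NMR Time-Domain Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A processing engine that converts vendor time-domain NMR data
    (Agilent, Bruker, 1D JCAMP-DX) or synthetic free-induction decays into
    referenced frequency-domain spectra stored in tiled sub-matrix files
    (.nv and .ucsf dialects).  Provides the standard per-vector operation
    catalogue (apodization, zero filling, Fourier and Hilbert transforms,
    phasing, baseline correction, linear prediction, solvent suppression,
    linear combination), chemical-shift referencing including indirect
    heteronuclear ratios, a per-dimension script interpreter with operation
    inversion (UNDODIM) and dimension skipping, real-valued iterative
    soft-thresholding reconstruction of non-uniformly sampled indirect
    dimensions, a synthetic FID simulator, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, parallel, stats, utils, tools
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
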