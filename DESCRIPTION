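Package: piezodyn
Title: Protein Dynamics Under Temperature and Pressure from Incoherent
    Neutron Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for elastic and quasi-elastic incoherent
    neutron-scattering studies of proteins under combined temperature and
    hydrostatic-pressure scans. Implements the reduction chain (transmission,
    empty-cell and buffer subtraction, vanadium normalization, detailed
    balance, temperature binning, energy rebinning), global two-state
    double-well fitting of elastic scans, Hall-Ross jump-diffusion plus
    localized-motion fitting of quasi-elastic spectra with instrument
    resolution convolution, elastic incoherent structure factor geometry
    fitting, Arrhenius and Vogel-Fulcher-Tammann thermal-law analysis, a
    forward synthetic-data generator with known ground truth, and ortholog
    sequence comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
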