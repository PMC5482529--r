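Package: pepgel
Title: Quantitative Characterisation of Peptide Hydrogelator Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for the multi-technique
    characterisation of small-molecule peptide hydrogelators. Fits one- and
    two-length-scale correlation models to reduced small-angle neutron
    scattering (SANS) profiles and derives cross-sectional fiber radii,
    mesh sizes and fractal dimensions; fits stretched-exponential (KWW)
    relaxation to dynamic light scattering autocorrelation traces; quantifies
    the NMR-visible free gelator fraction against a DSS internal standard and
    the extent-of-assembly order parameter; measures fiber cross-sections
    (height, half-height width, equivalent circular radius) and axial
    periodicity on AFM height maps; classifies oscillatory rheology frequency
    sweeps into sol, viscoelastic-fluid and gel regimes and assembles the
    concentration-temperature state diagram. A synthetic-data generator with
    known ground truth makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    withr,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
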