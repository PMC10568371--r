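Package: nmrspa
Title: Spatial Clustering and Statistical Total Correlation Spectroscopy
    for Untargeted NMR Metabolite Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated, untargeted analysis of one-dimensional 1H-NMR
    metabolomic spectra. A moving-window correlation landscape groups
    contiguous spectral datapoints into spatial clusters (SPA), with the
    window size selected from the partial autocorrelation function and
    the clustering threshold selected by prediction-strength cluster
    stability. Clusters are then coupled across the spectrum by
    statistical total correlation spectroscopy (STOCSY) and matched
    against a metabolite resonance library to produce per-metabolite
    detection ratios and identification calls. Includes a spectrum
    simulator with Lorentzian multiplets, chi-squared concentration laws
    and AR(1) noise, probabilistic quotient normalization, a statistical
    recoupling of variables (SRV) baseline clustering, and coverage and
    identification scoring against simulation ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
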