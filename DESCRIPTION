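Package: hgmrs
Title: In Vivo 2-Hydroxyglutarate Quantification from Proton MR Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect the oncometabolite 2-hydroxyglutarate (2-HG) in
    IDH-mutant glioma from in vivo proton magnetic resonance spectroscopy.
    Implements a standardized spectral post-processing chain (water-reference
    eddy-current correction, Hanning apodization, zero filling, Fourier
    transformation, frequency alignment, sixth-order polynomial baseline
    correction, zero-order phase correction), Gaussian peak fitting inside
    eight fixed chemical-shift windows, and the Glx3/Glx4 percentage-elevation
    statistic that reports 2-HG as the excess of the combined glutamate +
    glutamine + 2-HG resonance near 2.29 ppm over the pure glutamate +
    glutamine resonance near 2.35 ppm, normalized by the contralateral ratio.
    Includes a synthetic free-induction-decay simulator with known ground
    truth, cohort-level diagnostic statistics (Pearson correlation with
    bootstrap, predictive values, subgroup comparisons), a packaged clinical
    reference table, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
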