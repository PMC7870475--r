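Package: revcorr
Title: Reverse-Correlation Classification Images from Sinusoid Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reverse-correlation psychophysics with a parametric
    sinusoid noise basis. Noise images built from localized sinusoid patches
    at several spatial scales are superimposed on a template image and
    classified by an observer; the class-conditional noise statistics yield
    classification images (CIs), per-spatial-scale decompositions,
    per-parameter contribution statistics with Bonferroni control,
    reconstructed class prototypes, and a CI-weighted one-layer classifier
    with a permutation baseline. Synthetic linear-template observers with
    known ground truth allow the whole pipeline to be validated end to end;
    external classifiers plug in through a small adapter contract.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
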