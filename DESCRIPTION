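Package: icgn
Title: Integrated Contextual Gate Networks for fNIRS Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recurrent sequence classifiers for functional near-infrared
    spectroscopy (fNIRS) brain-computer interfaces, built around the
    integrated contextual gate network (ICGN) cell, in which every gate and
    the candidate activation receive the previous cell state and the memory
    cell is the candidate scaled by the sum of the three gate activations.
    Includes a from-scratch LSTM baseline, bidirectional wrappers,
    backpropagation-through-time training with verified gradients, modified
    Beer-Lambert conversion of two-wavelength absorbance to hemoglobin
    concentration changes, zero-phase band-pass filtering, block-design
    paradigm segmentation and labeling, balanced train/validation/test
    splitting, a synthetic block-design fNIRS generator with a canonical
    double-gamma hemodynamic response, and cohort-level statistics (pooled
    t-test, one-way ANOVA, Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
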