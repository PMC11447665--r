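Package: zonexplain
Title: Zone-Based SHAP and LIME Explanations for Spectral Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-agnostic explanations for classifiers of 1-D vibrational
    spectra (Raman, infrared). Instead of attributing a prediction to hundreds
    of individual wavenumber intensities, the spectral axis is segmented into
    contiguous zones bounded by the valleys between peaks, whole zones are
    perturbed as groups, and zone-level Shapley values (exact enumeration or a
    permutation-sampling approximation) and sparse LIME surrogate coefficients
    are computed against any model exposed through a simple
    batch-probabilities prediction contract. Ships waterfall, relevance,
    saliency-map and beeswarm summary visualisations, a synthetic
    Raman-edible-oil dataset generator with class- and bottle-level
    variability, and a small command-line workflow (simulate, zones, explain,
    summary).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    nnet,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
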