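Package: hemimacula
Title: Hemi-Macular GCL/IPL Atrophy Analysis for Lateralizing Retrochiasmal Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of macular optical coherence tomography (OCT)
    posterior-pole thickness grids for detecting and lateralizing
    retrochiasmal visual-pathway lesions in multiple sclerosis.
    Implements central 4x4 sector extraction from 8x8 posterior-pole
    grids, two-step thickness correction (control-mean centering plus an
    additive per-sector optic-neuritis offset), a homonymous hemi-macular
    atrophy classifier for ganglion cell layer (GCL) and inner plexiform
    layer (IPL) maps, paired diagnostic-accuracy evaluation against MRI
    and visual-field labels (sensitivity, specificity, predictive
    values, McNemar tests), an integer contingency-table reconstruction
    audit for rounded published statistics, and a synthetic cohort
    generator encoding retrograde trans-synaptic degeneration with
    contralateral (crossed-fiber) dominance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
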