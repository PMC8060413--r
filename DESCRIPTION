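Package: eprdist
Title: Spin-Label EPR Mobility and Distance-Distribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of site-directed spin-labeling EPR data for
    protein-complex structural studies. Implements continuous-wave
    nitroxide spectrum preprocessing and the low-field peak ratio (LFPR)
    mobility statistic with noise-based error bars; four-pulse DEER
    (PELDOR) distance-distribution recovery by Tikhonov regularization
    with non-negativity, L-curve corner selection of the regularization
    parameter, and background-ensemble uncertainty bands; and
    structure-model-based distance-distribution prediction from conformer
    ensembles via Kabsch superposition, gromos clustering and
    cluster-size-weighted averaging. A synthetic-data module generates
    two-component CW spectra, DEER traces and helical conformer ensembles
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    signal,
    jsonlite,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
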