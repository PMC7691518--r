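Package: cyclecoh
Title: Dense-Sampling Analysis of Hormone-Linked Functional Network Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating daily sex-hormone concentrations to the
    coherence and topology of functional brain networks in dense-sampling
    (one-session-per-day) designs. Node timeseries are band-limited with a
    maximal overlap discrete wavelet transform, pairwise association is
    estimated as band-averaged magnitude-squared coherence with per-day
    FDR thresholding, day-by-day edge coherence is regressed on
    standardized hormone series with nonparametric permutation thresholds,
    and network topology (weighted participation coefficient and global
    efficiency) is modelled against hormones with motion residualization,
    MAD outlier screening and FDR correction across models. A seeded
    synthetic-study generator emulating a 30-day menstrual-cycle protocol
    (cyclic hormone curves, a motion confound, and day-varying inter-node
    coupling) makes every stage testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
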