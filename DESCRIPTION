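Package: burstfit
Title: Bursty Transcription Models with Extrinsic Noise for Single-Cell
    mRNA Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the telegraph (two-state promoter) model of bursty
    transcription to single-cell mRNA copy-number data, in the bursty
    limit where copy numbers are negative-binomial, and extends it with
    log-normal cell-to-cell variation in burst frequency to capture
    extrinsic noise. Provides Bayesian MCMC inference of burst frequency,
    burst size and frequency dispersion with MAP estimates and credible
    intervals; decomposition of expression variance into intrinsic and
    extrinsic contributions via the law of total variance; mutual
    information between gene pairs with a permutation null; conversion of
    smFISH spot intensities into per-cell copy numbers using zero- and
    low-expression controls; and seeded synthetic-data generators
    (compound-model sampling, exact Gillespie simulation of the telegraph
    scheme, coupled two-gene pairs, synthetic spot tables) so the whole
    pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
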