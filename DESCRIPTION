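Package: pooldesign
Title: Evaluating Soil Sampling Designs and Pooling Strategies for Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-based evaluation of how soil sampling designs
    (number of subsamples, sampling area, depth) and sample pooling
    strategies (unpooled, soil pooling, DNA pooling) change
    metabarcoding-based biodiversity estimates. Provides a spatially
    explicit virtual-community generator (Thomas cluster processes with
    vertical stratification), virtual coring of twelve published sampling
    designs, a laboratory simulator covering soil compositing, DNA-extract
    mixing, extraction dilution, biased PCR with chimera-type artefact
    generation and sequencing, diversity kernels (Good's coverage, Hill
    numbers, analytic and Monte-Carlo rarefaction, Chao1, accumulation and
    extrapolation curves), the pooling-effect ratio statistic, a
    rectangular area-subsampling test, first-principles PERMANOVA,
    multivariate dispersion and Mantel correlogram routines, molecular
    artefact screening by indel and divergence rules, and a sample
    processing cost calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
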