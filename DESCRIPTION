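Package: axisdyn
Title: Time-Resolved Encoding-Axis Dynamics in Neural Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how visual neurons encode stimuli along linear
    axes in deep-network-derived feature spaces, and how those axes change over
    time. Provides a synthetic population generator with ground-truth tuning
    (including stimulus-gated axis switching and matched no-switch controls),
    PCA feature-space construction with per-dimension normalization,
    closed-form preferred-axis estimation with train/test evaluation and
    cross-category prediction, sliding-window axis timecourses with
    cosine-similarity matrices and tuning-flip detection, population statistics
    (face-selectivity d-prime, Treves-Rolls population sparseness, population
    separation index, dimensionality for 90 percent variance, single-stimulus
    axis-change score), orthogonal decomposition of emergent tuning directions,
    window-wise linear decoding with nearest-neighbour identification, and a
    small recurrent-network model of reversal via lateral inhibition.
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
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
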