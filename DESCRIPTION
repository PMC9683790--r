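Package: vipmode
Title: Event-Aligned Analysis of Cortex-Wide VIP Interneuron Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing event-aligned two-photon calcium imaging of
    VIP interneurons recorded while mice perform an auditory go/no-go task.
    Provides a synthetic session generator with full ground truth; dF/F
    computation, trial alignment and response-kinetics estimation;
    responsiveness classification (Lilliefors check plus one-tailed t-tests)
    with population synchronicity, reliability and stability statistics;
    PCA plus k-means temporal archetype clustering with feature projections;
    time-warped non-negative canonical polyadic (tensor component)
    decomposition; pupillometry and locomotion arousal-split analyses; a
    cross-validated lasso model with behavioural event kernels; orientation
    and direction selectivity indices; tile-based FFT motion correction with
    robust consensus displacement; soma-diameter morphometry; and closed-form
    scan-performance arithmetic for scanning-strategy comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    nortest,
    minpack.lm,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
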