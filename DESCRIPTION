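Package: bcinull
Title: Predicting the Distribution of Output-Null Neural Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying neural redundancy under a linear
    brain-computer-interface (BCI) readout. Fits a factor-analysis model of
    the intrinsic manifold to binned spike counts, decomposes factor activity
    into output-potent and output-null components of a velocity readout,
    predicts the per-time-step distribution of output-null activity under six
    candidate hypotheses (Minimal Firing, Minimal Deviation,
    Uncontrolled-uniform, Uncontrolled-empirical, Persistent Strategy, and
    Fixed Distribution), and scores the predictions with histogram, mean, and
    affine-invariant covariance error metrics together with split-half error
    floors and subspace variance-ratio analyses. Includes a closed-loop
    center-out BCI session simulator with configurable ground-truth coupling
    between output-null and output-potent activity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
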