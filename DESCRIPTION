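Package: pitrel
Title: Reliability Analysis for Pavlovian-to-Instrumental Transfer Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reliability analysis of Pavlovian-to-instrumental
    transfer (PIT) experiments. Provides a generative simulator of the PIT
    task (instrumental training with a performance-based stopping rule,
    Pavlovian conditioning, and a transfer phase with monetary cue values),
    estimators for the two behavioural PIT parameters (the interference
    error-rate difference and the motivational Poisson mixed-model slope),
    permutation-based split-half reliability with Spearman-Brown correction
    and Fisher-z aggregation, absolute-agreement intraclass correlations with
    confidence intervals, voxel-wise and region-of-interest reliability of
    first-level statistical maps, Jaccard overlap of thresholded maps, and a
    config-driven pipeline that produces full behavioural and neural
    reliability reports from simulated or user-supplied data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
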