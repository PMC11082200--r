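Package: cftnps
Title: Neural Pattern Similarity Dynamics of Episodic Counterfactual Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level representational-dynamics analysis of episodic
    counterfactual thinking (eCFT) in fMRI. Implements single-trial
    finite-impulse-response (FIR) pattern estimation within a
    Least-Squares-Separate (LSS) design, motion-outlier trial exclusion,
    atlas-based region-of-interest retention, two neural pattern similarity
    indices (the Recall-CFT similarity shift and the CFT-CFT similarity),
    two-step nuisance residualization, and per-region linear mixed-effects
    moderation models with Satterthwaite degrees of freedom, simple slopes,
    and false-discovery-rate correction. Includes a synthetic-study
    generator with known ground-truth index dynamics so the full pipeline
    can be exercised and calibrated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
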