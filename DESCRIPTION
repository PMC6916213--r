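Package: copdatlas
Title: Irregular Time-Lapse Segmentation and Atlas Visualization of COPD
    Progression from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models chronic obstructive pulmonary disease (COPD) progression
    from longitudinal free-text clinical notes. A four-layer sequence model
    (word embedding, long short-term memory recurrence, flatten, dense head)
    is trained by gradient descent to predict the time window before death in
    which a day's merged notes were written, and a sigmoid boundary head
    merges fixed initial time windows into irregular time-lapse segments.
    For the most recent segments before death, a latent Dirichlet allocation
    sampler extracts per-segment theme words and representative sentences,
    which are rendered as a "COPD atlas" on a spiral timeline against an
    equal-window baseline. Includes a synthetic note-corpus generator with
    planted stage vocabularies, linear-regression and support-vector-machine
    baselines, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
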