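Package: desconcord
Title: Validation of Presurgical fMRI Maps Against Intraoperative
    Stimulation Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores presurgical functional MRI maps (task-based GLM,
    seed-based resting-state connectivity, multi-echo resting-state)
    against intraoperative direct electrical stimulation (DES)
    coordinates.  Statistical maps are binarized by a deterministic
    k-means intensity rescaling with an automatic minimum-threshold
    rule, compared to DES sites via minimum Euclidean distances in
    world millimetres, and summarised with ROC curves, DeLong tests,
    binary agreement tables, Dice/Jaccard overlap, and a two-part
    logistic-lognormal mixed-effects model for semicontinuous distance
    data with correlated subject-level random intercepts.  A phantom
    generator produces synthetic subjects (activation truth, 4D BOLD
    series for four acquisition schemes, DES coordinate tables) so the
    whole analysis runs end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    Matrix,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
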