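Package: musyn
Title: Muscle Synergy Extraction and Shared-Synergy Analysis for Multi-Channel EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing muscle synergies in multi-channel surface
    electromyography (EMG) recorded during complex motor tasks. Provides EMG
    envelope extraction (zero-lag Butterworth band-pass, rectification,
    low-pass), phase time-normalisation and cross-task amplitude
    normalisation; non-negative matrix factorisation with best-of-restarts
    selection and total variance accounted for (tVAF); synergy-number
    selection by dual tVAF criteria; inter-participant similarity (cosine
    similarity, Pearson r with analytic critical values, cross-correlation);
    non-negative least-squares reconstruction of synergy vectors and
    activation coefficients across participants and tasks with randomized
    null comparisons; shared-synergy counting across tasks; and a synthetic
    EMG generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
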