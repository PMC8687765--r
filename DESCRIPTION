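Package: rhythmbeat
Title: Rhythm-Aware Heartbeat Classification with Tree-Regularized
    Bidirectional LSTMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end arrhythmia heartbeat classification that exploits the
    rhythm information carried by runs of consecutive beats. Provides discrete
    wavelet (db6) denoising of single-lead ECG, R-peak-anchored beat
    segmentation into fixed 235-sample windows, AAMI five-class annotation
    mapping, assembly of rhythm-preserving beat segments, a bidirectional LSTM
    sequence classifier trained with a tree-regularization penalty (a
    differentiable surrogate for the average path length of a decision tree
    distilled from the network), simulated-decision-tree interpretability
    (per-node class percentages, top-k feature points, reduced-feature
    retraining), per-class sensitivity/specificity/positive-predictive-value
    evaluation, and a synthetic arrhythmia generator (bigeminy, trigeminy,
    tachycardia rhythm grammars) so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
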