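Package: intrudetect
Title: Decoding Transient Memory Intrusions from EEG by Cross-Task
    Temporal Generalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect transient intrusive-memory events in EEG
    recorded during a Think/No-Think memory-suppression task, by
    generalizing per-timepoint random-forest classifiers trained on an
    independent attention task. Implements sliding-window multivariate
    decoding with cross-validated AUC timecourses (voltage and Morlet
    time-frequency features), cross-task temporal generalization with a
    permutation-null probability threshold, Gaussian-smoothed
    intrusive-memory-strength timecourses, cluster-based permutation
    inference over time, intrusion-regulation dynamics (intrusion slopes,
    suppression-induced forgetting, item-state transitions with linear
    mixed models), and a seeded synthetic-EEG generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    randomForest,
    jsonlite,
    data.table,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
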