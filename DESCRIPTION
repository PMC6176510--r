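Package: apcpmi
Title: Seizure Identification from EEG Channel Synchronization via
    Affinity-Propagation Partition Mutual Information
Version: 0.1.0
Authors@R: person("EEG", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures pairwise synchronization between multichannel EEG
    signals with an adaptive mutual-information estimator whose amplitude
    partitions are derived from affinity-propagation clustering of each
    channel's samples (APCPMI), assembles per-window channel-by-channel
    synchronization matrices (CMAPCPMI), and classifies windows as seizure
    or non-seizure with a cross-layer fully connected neural network
    trained from scratch by mini-batch momentum gradient descent.
    Includes equal-probability-partition mutual information as a baseline,
    window segmentation with class-balanced sampling, confusion-matrix
    metrics (sensitivity, specificity, accuracy, precision, G-mean,
    F-measure) and rank-based ROC AUC, a controllable synthetic
    multichannel generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
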