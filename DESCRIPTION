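Package: dtcn
Title: Deep Temporal Convolution Networks for Multivariate Time-Series
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification of multichannel, per-sample-labelled
    physiological time series (EEG, wearable-sensor signals) with deep
    temporal convolution networks (DTCN): time-delay windowing of the raw
    signal, temporally ordered overlapping mini-batches, concatenation
    sublayers that carry temporal context into the deeper layers of a
    pretrained feed-forward network, greedy restricted-Boltzmann-machine
    pretraining by contrastive divergence, and backpropagation through the
    non-differentiable concatenation operator by split-slide-add gradient
    routing.  Includes label-count pooling with deferred majority voting,
    complexity-matched plain-network baselines, k-fold cross-validation
    drivers, and a synthetic generator of Markov regime-switching
    multichannel signals for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    foreign,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
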