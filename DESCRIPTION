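Package: burstKinetics
Title: Promoter State Inference from MS2 Transcriptional Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers transcriptional bursting kinetics from single-nucleus
    MS2/MCP fluorescence time series. Simulates two- and three-state Markov
    promoter models (Gillespie), synthesizes frame-sampled fluorescence
    traces through a single-polymerase trapezoid kernel, deconvolves traces
    into individual Pol II initiation events with a genetic algorithm plus
    local optimization, estimates waiting-time survival functions
    (Kaplan-Meier with Greenwood confidence bands), fits multiexponential
    survival models with a mixed linear/log objective and parsimony-based
    selection of the number of promoter states, and reverse-engineers
    switching and initiation rates in closed form, including error
    intervals from suboptimal solutions and a cutoff Kolmogorov-Smirnov
    goodness-of-fit test. Also models postmitotic activation delays as a
    mixed-gamma (Erlang mixture) distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'promoter-models.R'
    'multiexp-params.R'
    'signal-kernel.R'
    'signal-synthesis.R'
    'deconvolution.R'
    'waiting-times.R'
    'multiexp-fit.R'
    'model-inversion.R'
    'gap-analysis.R'
    'pipeline.R'
    'show-methods.R'
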