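Package: pbspike
Title: Stimulus-Evoked Spike-Train Analysis for Parabrachial Recordings in
    Neuropathic Pain Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for extracellular single-unit recordings from
    the parabrachial complex in rodent models of trigeminal neuropathic pain
    (chronic constriction injury of the infraorbital nerve), together with the
    associated pain-behavior endpoints. Provides peristimulus time histogram
    construction with a 99 percent confidence band on baseline firing,
    detection of after-discharges, stimulus-evoked suppression and
    post-inhibitory rebound bursts, force-normalized response magnitudes,
    up-down (Dixon) 50 percent withdrawal-threshold estimation, grimace-scale
    and Hargreaves aggregation, the nonparametric group statistics used for
    sham versus injury contrasts, and an inhomogeneous-Poisson simulator that
    generates sessions with the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'core-model.R'
    'simulate.R'
    'psth.R'
    'detect.R'
    'metrics.R'
    'behavior.R'
    'stats.R'
    'pipeline.R'
    'show-methods.R'
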