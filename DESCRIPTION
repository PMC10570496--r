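Package: nmmstim
Title: Delayed-Feedback Stimulation in a Basal Ganglia Neural Mass Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a three-population neural mass model of the
    subthalamic nucleus (STN), external globus pallidus (GPe) and
    pedunculopontine nucleus (PPN), reproducing parkinsonian beta-band
    (~22 Hz) oscillations under a pathological coupling regime. Implements
    four closed-loop delayed-feedback stimulation strategies of the form
    w(t) = K * (v(t - tau) - v(t)) driven by the local field potential of a
    source nucleus and injected into a target nucleus, together with the
    evaluation metrics used to assess them: FFT power spectra with
    dominant-frequency extraction, an oscillation index (mean squared LFP
    deviation over the final simulated second) and an energy index (mean
    squared stimulation signal). Provides seeded forward-Euler integration
    with a compiled core, replicate-averaged parameter sweeps over
    stimulation intensity K and delay tau, suppression-island detection,
    YAML parameter presets and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
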