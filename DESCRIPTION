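Package: tdcsnet
Title: Spiking Network Model of tDCS-Induced Homeostatic Network Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clock-driven simulation of recurrent networks of current-based
    leaky integrate-and-fire neurons whose excitatory-to-excitatory
    connectivity is grown and pruned by a calcium-based homeostatic
    structural-plasticity rule. Transcranial direct current stimulation
    (tDCS) is modeled as a subthreshold membrane polarization applied to
    groups of excitatory neurons under uni-, bi- and tri-group montages,
    including repetitive on-off and alternating-polarity cycles. The package
    provides the measurement suite used to quantify stimulation outcomes:
    windowed group firing rates, group-resolved mean connectivity,
    triple-exponential fits of the relaxation-phase connectivity change, and
    the connectivity time integral.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
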