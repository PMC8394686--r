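Package: gcnet
Title: Granger-Causality Network Inference and Detection of Unobserved Hubs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers directed interaction networks from multichannel time
    series in the Granger-causality framework, using vector autoregressive
    (VAR) models as the substrate. Provides the time-domain directed partial
    correlation (DPC) with amplitude-adjusted Fourier-transform (AAFT)
    surrogate percentile-bootstrap significance, and the frequency-domain
    renormalized partial directed coherence (rPDC) with a chi-squared
    pointwise test. On top of edge inference it implements out-degree hub
    identification, systematic sub-network (leave-hub-out) scanning, and a
    feedback-structure heuristic that flags evidence for unobserved important
    components, together with a six-node benchmark system and a Monte Carlo
    power/coverage harness.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
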