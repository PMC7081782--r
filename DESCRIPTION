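Package: dcedge
Title: Consistent Differentially Correlated Edges in Longitudinal Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Edge-centric feature selection for longitudinal two-group gene
    expression studies. For every gene pair in a reference interaction
    network, within-group Spearman correlations are computed at each
    timepoint; pairs whose between-group correlation difference exceeds a
    threshold at every timepoint are called consistent differentially
    correlated edges (DCEs). Significance is assigned by patient-level
    permutation of group labels, the implicated gene signature is extracted,
    and a linear support-vector-machine classifier scores independent
    longitudinal validation samples. Includes a Gaussian-copula simulator
    that plants group-specific Spearman correlations on a known network so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
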