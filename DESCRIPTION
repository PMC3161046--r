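Package: somatlas
Title: Self-Organizing Map Portraits of Gene Expression Landscapes
Version: 0.1.0
Authors@R:
    person("somatlas", "developers", email = "somatlas@example.org",
           role = c("aut", "cre"))
Description: Transforms a genes-by-samples expression matrix into a
    two-dimensional metagene map using a self-organizing map (SOM),
    renders per-sample expression portraits in several contrast scales,
    segments over- and underexpression spot modules on the lattice,
    annotates them by hypergeometric gene-set overrepresentation, and
    supports metagene-based feature filtering (fold change, variance,
    local FDR), downstream hierarchical clustering and independent
    component analysis, entropy-based cluster specificity scoring, and
    second-level SOM mapping of samples. Includes a planted-module
    synthetic data generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    ape,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
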