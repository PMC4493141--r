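Package: cnar
Title: Constraint Network Analysis of Protein Rigidity and Thermostability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models protein structures as body-and-bar constraint networks and
    analyzes their rigidity with a 6-degree-of-freedom pebble game. Thermal
    unfolding is simulated by diluting hydrogen-bond constraints in order of
    strength; global indices (cluster configuration entropy, rigidity order
    parameter, phase transition temperature) and local indices (percolation
    profiles, rigid-contact stability maps, and the median stability of rigid
    contacts between residue neighbors) are computed along the unfolding
    trajectory. Ensembles of network topologies with fuzzy noncovalent
    constraints improve the robustness of predictions, and unfolding pathways
    are compared by k-medoids clustering of residue-wise percolation profiles.
    Includes fixtures (ideal helices, toy networks, a lipase A variant table)
    so all analyses run without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    cluster,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
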