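Package: ribotraffic
Title: Stochastic Simulation of Translation Elongation with Finite tRNA
    Recharging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kinetic Monte Carlo simulation of ribosome traffic on mRNAs,
    modelled as a multi-lattice totally asymmetric exclusion process with
    extended ribosomes. Codon-specific hopping rates are proportional to
    finite pools of aminoacylated tRNAs that are shared across all mRNA
    copies and recharged by Michaelis-Menten synthetase kinetics, so that
    both the supply of and the demand for each tRNA species shape
    elongation. Includes the closed-form analytic layer (supply/demand
    metrics, critical initiation rates for charged-tRNA depletion, the
    queueing-phase threshold for a fixed slow site, regime classification
    for designer transcripts), codon usage indices (RSCU, CAI, and the
    queueing likelihood index QLI), generators for synthetic gene sets and
    exactly solvable micro-instances, and an exact CTMC enumeration oracle
    used to validate the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
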