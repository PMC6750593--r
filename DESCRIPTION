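Package: ribocollide
Title: Stochastic Simulation and Analysis of Ribosome Collisions and
    Collision-Stimulated mRNA Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based stochastic simulation of eukaryotic translation on a
    codon lattice coupled to canonical mRNA decay (deadenylation, decapping,
    5'-3' exonucleolysis) and to collision-stimulated quality control at
    elongation stalls (abortive termination and endonucleolytic mRNA
    cleavage).  The exact Gillespie engine supports the traffic-jam, simple
    and collision-stimulated abortive-termination models as well as simple
    and collision-stimulated endonucleolytic-cleavage models, and reports
    protein synthesis rate and mRNA lifetime across initiation-rate sweeps.
    Companion analysis modules identify polybasic and polyproline
    stall-encoding windows in coding sequences, compute P-site coverage,
    metagene density and translation efficiency from ribosome-profiling
    summaries, and quantify pooled-reporter mRNA levels from barcode counts.
    Synthetic-data generators provide ground-truth fixtures for every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
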