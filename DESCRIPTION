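Package: deadenylate
Title: Stochastic Simulation and Quantitative Analysis of Pab1-Coupled
    mRNA Deadenylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic, event-driven simulation of poly(A) tail removal
    by the Ccr4-Not deadenylase complex acting on RNA bound by the
    poly(A)-binding protein Pab1, with virtual gel readouts (lane profiles,
    modal tail lengths, pause-band detection, bound fractions). Includes
    the accompanying quantitative procedures: one-site equilibrium binding
    and dissociation/association kinetic fits, and a transcriptional
    shut-off half-life pipeline with spike-in normalization, exponential
    decay fitting with exclusion rules, codon-optimality binning, Pab1
    occupancy statistics and ANOVA/Tukey bin comparisons. Seeded synthetic
    data generators for every input class make all stages testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
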