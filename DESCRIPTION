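Package: wgdsim
Title: Agent-Based Simulation of Whole-Genome Duplication in Digital Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based evolution simulator for studying the consequences
    of whole-genome duplication (WGD) under environmental challenge. Digital
    organisms carry digit-string genomes in which genes are discovered by a
    promoter grammar (TATA box, cis-element block, kind word, payload) and
    encode a gene regulatory network of transcription factors, a polymerase,
    signaling equations over environmental sensors, and structural actuator
    genes. Organisms forage on a toroidal food grid, replicate under
    substitution mutation and a conditional WGD operator, and die when energy
    is exhausted. The package provides the genome grammar and mutation
    operators, the per-step GRN dynamics, the food world with configurable
    food-removal challenge schedules, the organism life cycle, lineage and
    expression metrics (short- and long-term genetic distance, expression
    distance), and replicate experiment orchestration with ploidy-stratified
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
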