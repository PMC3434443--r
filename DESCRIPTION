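Package: motifchart
Title: Executable Statechart Models of Gene Regulatory Network Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and executes boolean, statechart-style models of the
    recurring motifs of gene regulatory networks: simple regulation,
    feedback loops, coherent and incoherent type-1 feedforward loops, and
    autoregulation. Each motif is a parallel composition of two-state
    (on/off) components whose transitions are guarded by boolean formulas
    over the presence or absence of genes and signals, updated under a
    synchronous discrete-time semantics. Provides a motif catalogue,
    deterministic simulation with timed input schedules, exhaustive
    attractor enumeration with basins, checkers for sign-sensitive delay,
    pulses, bistability and oscillation, BoolNet-style rule-file
    input/output, Graphviz DOT and SCXML statechart export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
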