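Package: epihier
Title: Coupled Genetic and Epigenetic Network Simulation of Cell-Fate
    Hierarchies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulator of cellular identity as attractors of
    coupled genetic and epigenetic regulatory networks. Master-regulator
    gene modules are arranged on a binary hierarchy (Cayley tree); each
    module carries a ternary epigenetic spin (silenced, bivalent, open)
    and a binary expression spin. The cell cycle alternates Metropolis
    equilibrations of an expression (Ising-like) Hamiltonian under a
    fixed epigenome and of an epigenetic (Potts-like) Hamiltonian under
    the resulting protein environment. Tools are provided for simulating
    self-initiated and cue-driven differentiation, transcription-factor
    induced reprogramming via random de-silencing perturbations (with
    outcome classification and efficiency estimation), a multi-gene
    module variant, four-point temporal correlation analysis, and
    parameter-sensitivity scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
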