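Package: stressosim
Title: Stochastic Boolean Simulation of the Bacillus subtilis Stressosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cellular-automaton model of stressosome activation in
    Bacillus subtilis. Builds the truncated-icosahedron lattice of 40 RsbR
    and 20 RsbS proteins, encodes neighbourhood-dependent phosphorylation
    rules for three hypotheses of RsbT kinase regulation (no cooperation,
    substrate activation, product activation), runs seeded Monte-Carlo
    ensembles of the stochastic Boolean dynamics under piecewise-constant
    stress schedules, and fits a hyperbolic-tangent response function to
    the resulting dose-response curves. Ships scenario presets that
    reproduce published stress time courses, phosphatase titrations and
    kinase-rate perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
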