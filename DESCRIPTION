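Package: loopdyn
Title: Conformational Ensemble Analysis of RNA Internal Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of conformational ensembles of RNA duplexes carrying
    tandem internal loops, as sampled by enhanced molecular dynamics.
    Provides glycosidic chi torsion computation and syn/anti state
    classification, symmetry-aware minimum-RMSD clustering (greedy leader
    and average-linkage hierarchical) with population percentages,
    windowed cluster-population convergence traces, Kullback-Leibler
    divergence convergence diagnostics on principal-component projections,
    two-dimensional potential-of-mean-force landscapes with basin
    detection, geometric hydrogen-bond classification of pyrimidine
    mismatches, and a synthetic ensemble generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
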