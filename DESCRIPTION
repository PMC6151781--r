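Package: iseScreen
Title: Filter-Based Bioactivity Indexing by Iterative Stochastic Elimination
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ligand-based virtual screening with ensembles of descriptor-range
    filters. Filters (conjunctions of closed numeric intervals over 2D
    physicochemical descriptors) are learned from labelled active/inactive
    molecule sets by iterative stochastic elimination, a stochastic
    combinatorial optimizer that repeatedly samples candidate filters, scores
    them by a rate-based Matthews correlation coefficient, and eliminates
    descriptor-range values over-represented among the worst solutions until
    the surviving space can be enumerated exhaustively. Screened molecules are
    ranked by the Molecular Bioactivity Index, an ensemble average of
    per-filter efficiency factors. Includes descriptor calculation from SMILES
    (Gasteiger partial charges, surface-area bins, Burden eigenvalues,
    connectivity indices), Tanimoto diversity and Lipinski/Oprea rule
    profiling, ROC/AUC and enrichment-factor evaluation, a seeded synthetic
    benchmark generator with planted descriptor boxes, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, jsonlite, Rcpp, ChemmineR, ChemmineOB
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), pROC, yaml
Config/testthat/edition: 3
biocViews: Cheminformatics, Classification
RoxygenNote: 7.3.3
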