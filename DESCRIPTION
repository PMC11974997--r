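Package: covfold
Title: Covariation-Constrained RNA Folding with Joint 3D Motif Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA consensus secondary structure, pseudoknots and
    recurrent 3D motifs (K-turns, GNRA tetraloops, loop E, junction motifs and
    others) jointly from a multiple sequence alignment. Significantly covarying
    column pairs, detected with an APC-corrected mutual information statistic
    against an empirical column-shuffle null, constrain both the canonical
    helices and the placement of motif models. The nested structure and motifs
    are inferred in a single pass by constrained CYK parsing of a probabilistic
    grammar with explicit 3-way and 4-way junctions, extended with motif
    sub-grammars whose terminals are segment profile HMMs scored on alignment
    column profiles. Pseudoknot and triplet layers are folded with a small
    auxiliary nested-pair grammar restricted to covarying pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
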