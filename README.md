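# covfold

Joint prediction of RNA consensus secondary structure, pseudoknots and
recurrent 3D motifs from a multiple sequence alignment, constrained by
covariation.

## The problem

Structural RNAs fold into canonical Watson-Crick helices connected by short
non-helical elements — GNRA tetraloops, K-turns, loop E, C-loops, junction
motifs — whose conserved non-Watson-Crick interactions organize the helices
into a 3D architecture. These *RNA 3D motifs* are short (4–20 nt), variable
in sequence, and carry little covariation of their own, so scanning for them
in isolation produces floods of false positives. Helices, by contrast, leave
a strong evolutionary fingerprint: compensatory double substitutions that
keep base pairs intact. `covfold` exploits this asymmetry: significantly
covarying column pairs pin down the helices, and the helices frame the loop
regions where motif models are allowed to fire. Helices, pseudoknots and
motifs are inferred together, in a single constrained parse of one
probabilistic model.

## The model

1. **Covariation.** Every eligible column pair is scored with weighted
   mutual information minus the average-product correction (APC). An
   empirical null from column-wise permutations of the alignment converts
   scores to E-values (expected per-alignment count of null pairs scoring as
   high). Pairs with E ≤ 0.05 are *positive* (must pair); variable pairs
   without covariation are *negative* (must not pair); external pair lists
   (e.g. converted R-scape output) can substitute for this stage.
2. **Layers.** Positive pairs are split into ordered layers, each a
   maximum-cardinality mutually nested subset (Nussinov-style dynamic
   program), until all positives are consumed. Layer 1 seeds the main
   structure; later layers hold pseudoknots and triplet interactions.
3. **Joint grammar.** Layer 1 is folded by CYK parsing of a stochastic
   context-free grammar with 12 nonterminals: helix start/stacking states,
   hairpin/bulge/internal loops, explicit 3-way and 4-way junctions, and a
   generic ≥5-way multiloop. Each motif from a descriptor file compiles into
   topological *variant* sub-grammars (1 hairpin, 2 bulge, 2 internal-loop,
   3 three-way, 4 four-way, 1 branch-segment) whose terminals are segment
   profile HMMs scored on alignment column profiles; the shipped 51-motif
   set yields 96 variant models and a 108-nonterminal joint grammar. A loop
   class with generic probability `p` and class fraction `f` keeps
   `p(1-f)` on the generic rule and gives `p·f/n` to each of its `n` variant
   models: with the trained generic hairpin probability 0.3475 and `f = 0.4`
   over 15 hairpin motifs, the generic rule keeps 0.2085, the class receives
   0.1390, and each motif 0.0093.
4. **Pseudoknot layers.** Layers ≥ 2 are folded with a small unambiguous
   nested-pair grammar in which only that layer's positives and their
   immediate stacking neighbours are pair-eligible.
5. **Support.** Each placed motif is flagged *covariation-supported* when at
   least one of its bounding helices contains a positive pair.

The grammars parse *probabilistic sequences*: emission scores are expected
log-probabilities under each column's residue distribution, so a whole
alignment is folded at once. The CYK/inside kernels are implemented in C++
(Rcpp); everything else is R.

## Worked example

Plant a perfectly covarying 4-bp hairpin closed over a GNRA tetraloop in a
20-sequence, 30-column synthetic alignment, then fold it against the shipped
51-motif set:

```r
library(covfold)
spec <- plant_spec(length = 30, n_seqs = 20,
  helices = list(list(pairs = cbind(8:11, 19:16), rate = 1.0)),
  motifs = list(list(name = "GNRA", spans = list(c(12, 15)),
                     consensus = "GNRA")),
  seed = 7)
gp  <- generate_plant(spec)
res <- fold_rna(gp$aln, motifs = default_motif_file(),
                config = fold_config(cov = covariation_config(seed = 7)))
print(res)
#> FoldResult: 1 layer(s), 4 positive pair(s), 1 motif(s)
#> <<<.<<<<<<<....>>>>>>>.....>>>
res$motifs[, c("motif", "variant", "class", "segments", "support")]
#>   motif variant class             segments support
#> 1  GNRA       1    HL 12..12;13..13;14..15    TRUE
```

All four planted pairs come back positive and forced into layer 1 (columns
8–11 against 19–16, visible as the inner stem of the structure string); the
GNRA model is placed exactly on the planted loop (columns 12–15, segments
G | N | RA) and is covariation-supported because its bounding helix contains
covarying pairs. `write_stockholm(gp$aln, res, "out.sto")` writes the
annotated alignment; `write_motif_report(res, "motifs.tsv")` the TSV report.

The same pipeline is available from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "covfold.R", package = "covfold"))') \
    fold my.sto --nshuffles 200 --seed 7 --out-prefix my
```

with subcommands `fold`, `covary`, `shuffle`, `validate-motifs` and `train`.

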