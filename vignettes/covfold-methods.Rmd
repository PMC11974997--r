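---
title: "Methods: covariation-constrained RNA folding with joint 3D motif annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covariation-constrained RNA folding with joint 3D motif annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covfold)
```

## Overview

`covfold` predicts a consensus RNA secondary structure — nested helices,
pseudoknots and triplet contacts — jointly with the placement of recurrent
3D motifs (hairpin, bulge, internal-loop, junction and branch-segment
motifs), for a multiple sequence alignment. The central assumption is the
usual one of comparative RNA analysis: conserved base pairs accumulate
compensatory double substitutions, so statistically significant covariation
identifies helices with high confidence, while 3D motifs — short and mostly
non-covarying — are best located *relative to* those helices rather than by
free sequence scanning. The pipeline therefore runs in five stages:
covariation classification, layer decomposition, constrained joint parsing
of layer 1, pseudoknot-layer folding, and assembly with covariation-support
flags.

## Covariation statistic and its calibration

For columns $i,j$ the raw statistic is the weighted mutual information (in
bits, gap-pairs excluded) of the joint residue distribution, minus the
average-product correction $\mathrm{APC}(i,j) = \bar m_i\,\bar m_j / \bar m$
which removes background correlation shared by many pairs. Significance
comes from an empirical null: the corrected scores of all eligible pairs in
`n_null_shuffles` column-wise permutations of the alignment (each column's
residues permuted independently, preserving composition). The E-value of a
pair is the pooled count of null scores at or above its score divided by the
number of shuffles — the expected per-alignment count of equally extreme
null pairs — and a pair is **positive** when this E-value is at most
`evalue_threshold` (default 0.05).

A pair is **negative** — disallowed from pairing — when it is not positive
but shows enough substitution activity that covariation would have been
visible: the power proxy $1 - \exp(-\lambda \min(s_i, s_j))$, with $s_c$ the
weighted minority-residue count of column $c$ and $\lambda = 0.5$, must
reach `power_threshold` (default 0.95). The proxy and its calibration are a
design decision of this package: external covariation software defines
negatives through its own power analysis, and `load_external_pairs()`
accepts such classifications verbatim. Columns with gap fraction at or
above 0.5 are never positive or negative: profile columns dominated by gaps
carry no pairing signal.

Two practical notes, both visible in the test suite. First, mutual
information is a *per-site* quantity: adding sequences whose substitutions
are consistent with the covariation pattern never lowers it, but an added
sequence that breaks the one-to-one pairing pattern (a G–U realization on
top of an existing G–C) genuinely lowers it — as it also lowers the
G statistic. Second, at the 0.05 per-alignment E-value the statistic needs
roughly 15 or more sequences to separate a perfectly covarying pair from
the small-sample MI bias of shuffled columns when the background itself is
variable; the planted fixtures in the tests use 16–20 sequences, the size
of a small Rfam seed alignment.

## Layer decomposition

Positive pairs are split into ordered layers, each a maximum-cardinality
mutually nested, column-disjoint subset of the remaining pairs, found by a
Nussinov-type dynamic program over pair counts (each positive pair has
weight 1; the spec of the method leaves helix-level versus pair-level moves
open, and pair-level is used here). Ties are broken toward the
lexicographically smallest sorted pair list by always pairing the leftmost
column with its smallest admissible partner during traceback, which makes
the decomposition deterministic. A column that participates in two positive
pairs (a triplet) necessarily lands in two different layers; layer 1 is
verified against exhaustive subset search in the tests.

## The joint grammar

### Base grammar

The base folding grammar has 12 nonterminals: a start/transit state,
helix-start and stacked-pair states (two pair-emission contexts, so fresh
and stacked pairs have separate 16-entry tables), a loop selector, hairpin
and bulge unpaired-run states, explicit 3-way and 4-way junction states, a
generic ≥5-way multiloop, and branch / trailing-branch states. It is
unambiguous: a given arrangement of pairs and motif annotations derives in
exactly one way, which the tests check by sampling derivations and counting
matching parses in an exhaustive enumeration. The published trained value
available for this grammar family is the generic hairpin-loop probability,
0.3475, and the shipped defaults pin it; all other rule probabilities and
emission tables are hand-curated (Watson-Crick/wobble-favouring pair tables,
more concentrated in stacking context; geometric run lengths). A counting
trainer (`train_by_counting()`) re-estimates every parameter from
structure-annotated Stockholm files via the unique constrained derivation
of each structure, with Laplace smoothing.

### Motif models

A motif descriptor names its type and the consensus of each segment. Each
segment becomes a profile HMM with emit-on-transition semantics: per
consensus position, residues outside the IUPAC code's set get probability
$10^{-4}$ and residues inside share the remainder equally; one geometric
insert state sits at every junction between match transitions; matches can
be deleted with probability $\delta = 0.01$ (the deletion rate is a design
default; only its existence is specified). The insert self-transition is
solved analytically so the expected emitted length is exactly
$k + \min(0.1k, 1.5)$ for consensus length $k$ — the cap is implemented by
solving the geometric rate, not by truncation — and an empty segment gets
expected length 0.1 so insertions remain possible. Deletions remove
$k\delta$ residues in expectation, and the insert rate compensates for
this, keeping the total expectation exact.

Each motif compiles into one sub-grammar per topological variant —
1 (hairpin), 2 (bulge: left/right), 2 (internal loop: which strand attaches
5′), 3 and 4 (junction rotations), 1 (branch segment) — with the bounding
Watson-Crick helices always emitted by the base grammar, never by the motif.
Integration reallocates prior mass per loop class: the generic production
with probability $p_c$ keeps $p_c(1-f_c)$ and each of the class's $n_c$
variant models receives $p_c f_c / n_c$ (maximum-entropy split), with class
fractions HL 0.4, BL 0.4, IL 0.5, J3 0.2, J4 0.2, BS 0.2. For bulges, whose
left and right variants attach to different generic productions, the
allocation is applied per production so probability is conserved rule by
rule. Branch-segment motifs attach at the multiloop branch nonterminal and
are therefore available in every junction. The shipped descriptor file is a
set of 51 motif architectures curated in-house from the motif literature
(15 hairpin-loop, 3 bulge, 23 internal-loop, 5 three-way, 3 four-way, 2
branch-segment), expanding to 96 variant models and a 108-nonterminal
grammar; it is a plain text file and fully user-replaceable.

### Parsing profiles under constraints

The grammars generate probabilistic sequences: the emission score of a
column with (gap-renormalized) residue distribution $f$ is
$\sum_x f(x)\log e(x)$, pair emissions analogously over the 16-entry table,
and segment HMMs are scored by their forward probability over the covered
span. Gap mass is simply excluded from the renormalization, so chart
indices always align with alignment columns; the documented alternative of
gap-weighted length penalties was rejected for complexity. CYK and inside
run in $O(L^3 M)$ with shared C++ kernels (max-plus versus log-sum-exp);
multi-atom rules are evaluated by a suffix dynamic program over split
points. Constraints enter through the score tables: forbidden pairs get
$-\infty$ pair scores, columns of forced pairs get $-\infty$ unpaired and
HMM emission scores, so any finite-score derivation realizes every forced
pair. When constraints admit no parse the package raises an explicit
"no valid structure" error. Traceback ties break deterministically: first
rule in declaration order, then smallest split point. Layers ≥ 2 use a
four-nonterminal unambiguous nested-pair grammar in which only the layer's
positives and their immediate stacking neighbours are pair-eligible — a
documented choice; whether the original cascade extends such helices
further is left open by its description.

Cross-layer positives are *forbidden* (not merely unforced) in layer 1, so
each positive pair is realized in exactly one layer. When a later layer
would re-use a column already annotated (a triplet), the structure string
keeps the earlier annotation and the extra pair is reported separately,
because a single WUSS string cannot express two partners for one column.

## Synthetic fixtures: what they do and do not emulate

The generator plants helices and motifs on a star phylogeny: every sequence
derives independently from one ancestor; helix pairs co-mutate to random
Watson-Crick/wobble pairs at a per-sequence covariation rate; motif columns
are drawn from the motif consensus with a small deviation rate (default
0.02); background columns mutate at 0.05. This produces the signal
structure the method relies on (covarying helices, conserved motif
sequence, variable background) but none of the confounders of real
alignments: no phylogenetic correlation between sequences, no alignment
errors, no indels, no base-composition skew. Passing tests therefore
demonstrate the machinery — constraint propagation, placement, calibration —
not field performance on Rfam-scale data. Two spec-level idealizations do
not survive contact with the probabilistic model and are tested in their
attainable forms: with *zero* background mutation the constant flanking
columns carry no negative-pair evidence and the grammar legitimately pairs
WC-compatible constant columns, so "exact" recovery is asserted as planted
pairs recovered plus exact motif placement; and the covariation-ablation
comparison is run in the single-sequence regime (covariation supplied
externally from the parent alignment) because an unconstrained fold of a
20-sequence profile places almost no motifs at all, making a false-positive
comparison vacuous.

## Problem sizes used by the test suite

Deterministic checks run on toy inputs. The randomized checks use: 100
random (grammar, sequence ≤ 10 nt) instances for CYK/inside against
exhaustive enumeration; 15 sampled derivations (≤ 10 nt) for unambiguity
against a grammar with the GNRA and K-turn models integrated; 200 random
instances of ≤ 12 pairs for layer-1 maximality against exhaustive subset
search; 20 replicates × 2 sequences of a 46-column double-plant (GNRA +
K-turn) for the ablation direction; 50 column-shuffled fixtures for the
null control; and $10^5$ Monte-Carlo draws for the segment-HMM length
calibration. These sizes were chosen so the full suite exercises every
statistical claim while remaining a routine desk run.

## Numerical choices

Log-space throughout, with `-Inf` as the impossible-score sentinel;
log-sum-exp is computed pairwise with the max factored out. Rule
probabilities must normalize to 1 within $10^{-9}$ per nonterminal or the
parser refuses the grammar. The R traceback recomputes the same sums as the
C++ chart fill in the same order, with a $10^{-9}$ tolerance as a guard.
Coordinates are 1-based everywhere (internally and in reports), matching R
indexing; external pair lists are 1-based as well. Sequence weighting
defaults to position-based (Henikoff) weights, with `"none"` available for
exact toy arithmetic — the weighting scheme is unspecified in the method's
description and is a design decision here.

## Known limitations

The covariation stage is a self-contained stand-in, not a phylogenetic
null: its E-values are empirical and its negative-pair rule is a calibrated
proxy, so for real alignments an external analysis (R-scape) supplied via
`load_external_pairs()` is preferable. Motif priors are fixed fractions,
not trained. The descriptor set is an independent curation; consensus
strings for the less-characterized motifs are approximate. Junction motif
variants are modelled as attachment rotations, one of several defensible
readings of multi-strand variant topology. The $O(L^3 M)$ parser is
practical to a few hundred columns with the full 96-variant grammar;
Rfam-scale surveys and drawing output are out of scope.
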