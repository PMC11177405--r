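---
title: "Resolving a multi-isotype gene family in an allohexaploid genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving a multi-isotype gene family in an allohexaploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analytical problem

An allohexaploid genome carries three diverged subgenomes (here G1, G2, G3,
standing for the N⁶, N⁷ and H⁷ subgenomes of *Camelina sativa*). A
conserved family such as the tubulins then exists in up to three homeologous
copies per isotype, on top of whatever tandem or transposed duplicates and
pseudogenes accumulated after polyploidization. Isotypes are *orthologous
lineages* finer than phylogenetic classes, and two distinct isotypes can
encode practically identical proteins; any single line of evidence —
sequence similarity, phylogeny, or position alone — misclassifies some of
them. The package therefore cross-references four kinds of evidence:

1. **similarity + motifs** (`mine_family`) to delimit the family,
2. **collinearity** (`find_anchors`, `chain_collinear`) to identify
   homeologous chromosomal segments,
3. **ancestral blocks** (`infer_block_borders`, `assign_gene_to_block`) to
   distinguish "same ancestral locus" from "relocated copy",
4. **phylogeny + locus context** (`nj_tree`, `assign_class_by_clade`,
   `context_similarity`, `resolve_isotype`) to name isotypes.

## The models and their assumptions

### Local alignment and E-values

`smith_waterman()` is exact Smith–Waterman under affine gaps (BLOSUM62,
open 11, extend 1; a gap of length L costs 11 + L). E-values follow
Karlin–Altschul, `E = K·m·n·e^{−λS}`, with the published gapped constants
(λ = 0.267, K = 0.041). They are approximations used **only for
thresholding** at the classic 1e-5 cutoff; we never interpret them as
probabilities. The BLAST word length is kept as a configuration echo — at
desk scale the alignment is exhaustive, and a 5-mer prescreen (a target
must share ≥ 5 five-mers with the query union) merely skips alignments
that cannot approach the threshold. Unknown residues score 0 against
everything.

### Motif confirmation

Conserved-motif scanning stands in for external motif/domain databases:
each reference isotype trains 11 position-weight matrices of width 15 at
evenly spaced positions (pseudocount 0.2); a protein is family-like when at
least 8 motifs exceed 60 % of the weakest training score at
order-consistent positions. The 60 % threshold was chosen from the score
geometry — a family member at the simulator's deepest divergence loses a
few points per window, a random protein scores near zero — and is *not*
tuned to any test outcome.

### Collinear chaining

Anchors are reciprocal best hits between two gene sets. Chains are
maximal-scoring runs over gene-order rank pairs, strictly monotone on both
axes, with rank gaps ≤ 25 and ≥ 5 anchors (common collinearity-tool
defaults; the underlying algorithm is the MCScanX-style dynamic program).
Greedy extraction by chain score with fixed tie-breaks makes the result
deterministic.

Because SW scores are symmetric, two identical gene sets always produce at
least one mutual-best pair — "self-comparison yields no anchors" is not
attainable as an absolute, and the tests assert the RBH definition
(mutuality, no self-pairs, one anchor per gene) instead.

### Homeolog grouping and the twin-isotype rescue

Family genes joined by chain-supported anchors merge into groups under the
constraint of one gene per subgenome (conflicts resolved by anchor score).
Twin isotypes are the deliberate hard case: the default family carries
TUA5 as an identical-sequence local duplicate of TUA3, so an RBH between
subgenomes is a coin flip between the twins. The group detector therefore
adds a *collinear-position rescue*: the chain covering a gene's
neighbourhood projects its rank interval onto the partner chromosome, and
a unique same-family gene inside the projection joins the group. This is
the synteny cross-referencing that motivates the whole design; without it
twin triplets cannot be recovered by any sequence-only rule.

### Ancestral-block reconstruction

Block-labelled syntelog pairs (the published ACK assignment is the
real-data analogue; the simulator emits its own truth labels) are
transferred onto anchors, and each chromosome's anchor sequence is
segmented into maximal one-label runs tolerating ≤ 2 contiguous foreign
anchors (logged as interlopers). Borders between adjacent runs sit at the
midpoint of the inter-anchor gap; gaps above 50 kb stay unassigned, and
runs under 3 anchors are flagged minor fragments rather than dropped.
Genes are allocated to blocks by their **5′-end coordinate**. The
midpoint rule is a declared convention — no border can be placed more
precisely than one intergenic interval without extra data, which is
exactly the tolerance the recovery tests assert.

### Relation classification

Rules apply in order: (1) different subgenomes + chain support + block
match → homeolog (disrupted homeolog if a member is a pseudogene);
(2) same subgenome + same block + ≤ 1 Mbp → tandem paralog (the cap
encloses the observed sub-megabase tandem case with margin); (3) same
subgenome + different block → transposed paralog; (4) different
subgenomes + different isotype lineages → homeoparalog; (5) cross-species
+ chain support + block match → ortholog. Anything unresolved is labelled
by best context similarity with a low-confidence flag, so the classifier
is total. Homeology precedes paralogy because homeologous context can
mimic paralogy but not vice versa.

### NG86 Ka/Ks

Synonymous site counts enumerate all nine single-nucleotide neighbours per
codon; neighbours creating stops are excluded from numerator and
denominator and the remaining fractions are renormalized ×3, so S + N = 3
per codon exactly (GGG carries 1.0 synonymous site, TTT carries 1/3).
Multi-difference codons average over all orderings of single steps with
equal weights, excluding pathways through stop codons (all pathways are
used if every one is blocked). Proportions are Jukes–Cantor corrected;
`ps ≥ 3/4` is reported as an undefined (saturated) distance, and Ks = 0
flags the ratio undefined rather than infinite. The per-codon tables are
verified against an independent enumeration oracle for all 61 sense
codons.

### Neighbor joining

Saitou–Nei with the Q criterion; ties broken by the lexicographically
smallest label pair; negative branch estimates clamped to zero with a
note. The implementation exactly recovers additive matrices (tested on 100
random tree metrics). Clade labelling midpoint-roots the tree (outgroup
rooting when an outgroup is supplied) and returns the label of the
smallest reference-containing ancestral clade, or "ambiguous" when that
clade mixes labels — ambiguity is *expected* for twin isotypes and defers
to locus context.

### Protein alignment

Pairwise global alignment uses exact Needleman–Wunsch. The multiple
aligner is a simple progressive scheme (guide order from average-linkage
clustering of 3-mer cosine distances, profile–profile merges with a linear
gap penalty) — a declared stand-in for heuristic aligners, adequate
because the family's proteins are nearly equal length and > 85 %
identical. It is not suitable for distant homology.

### Expression

Heatmap ordering follows the usual display convention: rows are z-scored
(constant rows become all-zeros, noted) before Euclidean average-linkage
clustering; leaf order is smaller-cluster-first with label tie-breaks, so
it is invariant to input row order. Contributions use **raw** values —
normalizing per gene would destroy exactly the quantity of interest — and
default to functional genes only, with explicit exclusions for members of
unclarified origin. Salt fold changes use a pseudocount of 1 and the 1.5×
threshold taken from the observed 1.5–3× range; calls are monotone in the
stress values.

## What the synthetic world does and does not establish

The generator states one world: 3 ancestral chromosomes × 3 blocks × 30
genes; 18-isotype family (6 TUA, 10 TUB, 2 TUG) with class-specific exon
counts; divergence 0.06/0.08/0.04 substitutions per site; ω = 0.05;
event rates loss 0.02, pseudogenization 0.05, tandem 0.01, transposition
0.01 per family gene per subgenome; lognormal expression (meanlog log 50,
sdlog 0.6, gene noise 0.1) with subgenome bias (1.15, 1.20, 0.80) and
salt fold-change 2 on TUB1/TUB7. Filler genes are 300-codon single-exon
ORFs evolving under the same process so anchors are realistic. Start and
stop codons are held fixed so functional genes remain valid ORFs; the
mutation model is codon-acceptance (synonymous accepted, nonsynonymous
accepted with probability ω, stops rejected), which gives direct ω control
without a full codon substitution matrix.

A green recovery suite therefore establishes that the pipeline's logic is
correct *under* this world: perfect family/filler discrimination, ≥ 95 %
triplet recovery with exact twin resolution, border placement within one
intergenic interval, exact salt-call recovery. It does **not** establish
robustness to real-genome phenomena the generator omits: repeats and
segmental duplications, chromosome rearrangements beyond block shuffling,
annotation errors, UTR/alternative-splicing structure, or expression
replicate noise. The accession-based checks that would probe real data
require downloading the *C. sativa* assembly and are out of scope offline;
the packaged inventory fixture (57 genes: 17 α, 34 β, 6 γ with IDs,
lengths, exon counts, classes, subgenomes) carries the desk-scale
real-data checks.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open in memory, 1-based inclusive in GFF3 on
disk; round-trips are bit-exact. Translation stops at the first stop
codon; pseudogene diagnosis fires on premature stops, frameshifts
(length mod 3 ≠ 0), or products < 60 % of the reference (a threshold that
separates a ~40 % fragment from a 98.7 % near-full protein). Empty CDSs,
zero-comparable-site pairs, all-zero expression columns, single-subgenome
blocks and proteins shorter than a motif all have defined, tested
behaviours (fatal, flagged, or degenerate-value) rather than silent NAs.

## Known limitations

* E-values are scale approximations; do not compare across search spaces.
* The progressive aligner assumes near-full-length, highly similar
  proteins.
* RBH + rescue assumes each isotype appears at most once per block per
  subgenome; heavily nested tandem arrays would need a different anchor
  model.
* The NG86 convention (stop-exclusion renormalization) differs from some
  tool implementations by up to a few per cent in Ka/Ks — comparisons
  against other software should carry a tolerance of that order.
* The simulator's block borders are exact by construction; real border
  uncertainty is larger than one intergenic interval wherever anchor
  density drops.
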