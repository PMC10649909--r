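---
title: "Chemical-space-network pharmacology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-space-network pharmacology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csnpharm)
```

`csnpharm` implements a network-pharmacology workflow for natural-product
compound libraries, organised around a *chemical-space network* (CSN): a graph
whose nodes are compounds placed by a 2-D embedding of their fingerprint
similarities and whose edges join compounds closer than a global distance
threshold. Around that core sit the standard network-pharmacology stages:
disease-gene filtering, target-set intersection, PPI hub ranking by Maximal
Clique Centrality, hypergeometric enrichment, a Pearson correlation screen,
and HOMO–LUMO descriptor handling. This vignette explains each model, the
parameters that matter, and the design decisions that were genuinely open.

## Fingerprints and similarity

Compounds enter as SMILES strings. Open Babel (via ChemmineR/ChemmineOB)
parses and canonicalizes them; duplicate canonical structures are dropped with
a warning, because supplementary tables routinely repeat isomers under
formatting variants. The package then computes hashed circular
(Morgan/ECFP-type) fingerprints itself: each atom receives an initial
invariant (atomic number, heavy-atom degree, bond-order sum, ring
membership), which is iteratively refined for `radius` rounds by hashing it
together with the sorted (bond order, neighbour invariant) pairs. Every
(atom, radius) environment whose bond set grew emits an identifier, and
identifiers are folded modulo `nbits`. Two configurations coexist, mirroring
common practice: 2048 bits for similarity calculations and 1024 bits for the
embedding input, both at radius 2.

Two caveats are deliberate. Stereochemistry is ignored: the invariants carry
no chirality or cis/trans flags, so `[C@H]` variants hash identically — a
documented limitation that none of the downstream contracts depend on. And bond orders are as kekulized by Open
Babel rather than aromatic-perceived, so bit *positions* differ from other
toolkits' — all downstream quantities depend only on bit-set overlaps
computed within one library, which are toolkit-internal.

Similarity is the Dice coefficient on on-bit sets,
$\mathrm{Dice}(a,b) = 2|a \cap b|/(|a|+|b|)$, computed exactly; two empty
fingerprints are an error because $0/0$ is undefined, and any valid molecule
has at least one environment.

## Embedding and the 1/24 rule

The library is embedded in 2-D by t-SNE on the precomputed distance matrix
$1 - \mathrm{Dice}$. No t-SNE implementation ships with the package's
dependency set, so an exact $O(n^2)$ implementation is included: per-point
bandwidths calibrated by bisection to the target perplexity
(default $\min(30, (n-1)/3)$), early exaggeration 12 for the first 250 of 500
iterations, momentum 0.5/0.8 with adaptive gains, learning rate 20, and a
per-point step-norm clip of 5. The clip and the moderate learning rate matter:
libraries with many near-duplicate rows have very peaked affinities, and
larger rates intermittently send the layout into a runaway expansion from
which gradients cannot recover. These settings were validated against an
independent reference t-SNE on identical distance matrices.

Determinism is taken seriously: the layout is initialized not from the global
RNG but from a hash of (seed, compound id), and the input is canonicalized to
id-sorted order before any arithmetic. Identical (library, seed) pairs
therefore give byte-identical coordinates *regardless of input row order* —
floating-point summation order would otherwise leak row order through the
optimizer's chaotic dynamics.

The CSN joins two compounds iff their embedded Euclidean distance is strictly
less than $\theta = D_{\max}/24$, where $D_{\max}$ is the diameter of the
embedded set; each edge carries the Dice similarity of its endpoints.
Clusters are the connected components of this graph ("all molecules are
traversed"), i.e. single-linkage transitive closure; singletons are clusters.

A scale caveat belongs here, because it constrains what the synthetic tests
can show. The 1/24 rule compares within-family embedding spread against the
global diameter. For a t-SNE layout of only ~20 points, family blobs occupy a
few tenths of the diameter — 2–5 times $\theta$ — for *any* correct optimizer
(we verified this with an independent implementation), so the rule only
resolves families once the library is at the scale of real database
retrievals. The synthetic generator's default library (6 families of 10 plus
10 unrelated singletons, 70 compounds) reflects that scale; running the
clustering stage on a printed ten-compound excerpt of a larger study library
yields singletons, as it must.

## Cluster scores and representatives

Each member's *mean within-group similarity* is
$\mathrm{MWGS}_i = \left(\sum_{j \in C} S_{ij} - 1\right)/n$, where the sum
runs over the member's cluster including the self-similarity of 1, which is
then subtracted. A singleton scores 0 and a perfect cluster attains
$(n-1)/n$, so MWGS is always below 1. The typeset form of this statistic is
ambiguous between this reading and a reciprocal one; the reciprocal reading
would nominate the *least* similar member as representative, contradicting
its purpose, so the subtraction reading is used.

Closeness centrality is computed on the full network (all components) from
unweighted shortest paths with the Wasserman–Faust scaling
$\frac{k-1}{n-1}\cdot\frac{k-1}{\sum_j d_{ij}}$, where $k$ is the node's
component size and $n$ the network size. This keeps values in $[0,1]$ and
comparable across components; isolated nodes score 0. The representative of a
cluster is its member of maximal closeness, with ties broken by maximal MWGS
and then lexicographic id; the MWGS-maximal member is reported alongside,
since both nomination rules appear in practice and they can disagree.

## Targets, intersections, hubs

Disease gene tables are filtered with strict per-source thresholds (defaults:
DisGeNET-style score > 0.1, GeneCards-style score > 5, PharmGKB-style keep
all) and unioned with deduplication. Differential-expression calls from three
methods are combined by a k-of-3 vote per direction (default k = 3, i.e.
intersection); the consensus rule is configuration because upstream studies
rarely state it. Gene identity is the uppercased symbol — alias resolution
needs an external database and is out of scope. Compound relevance is the
three-way intersection compound-targets ∩ disease genes ∩ DEGs, and the
cross-compound core is the intersection of those sets (the centre of the
petal diagram).

PPI edge lists (STRING-style, optional confidence column, default cutoff 0.4
= STRING "medium") become undirected simple graphs. Hubs are ranked by
Maximal Clique Centrality,
$\mathrm{MCC}(v) = \sum_{C \in S(v)} (|C|-1)!$ over maximal cliques $C$
containing $v$, implemented from the formula with igraph's Bron–Kerbosch
enumeration underneath. For a node whose neighbourhood induces no edges this
reduces to its degree (each incident edge is a maximal 2-clique contributing
$1! = 1$); isolated nodes score 0 — the singleton "clique" is excluded, since
counting it would give every isolated node a spurious score of $0! = 1$.
Top-k selection (default 10) breaks ties lexicographically and never expands
past k; the cross-compound hub union records which compounds contributed each
gene.

## Statistics

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ summed on the log-binomial scale (implemented directly, and
cross-checked in the tests against both exhaustive enumeration and the
standard distribution function), with Benjamini–Hochberg adjustment via
`stats::p.adjust`. Significance requires *both* p < 0.01 and q < 0.01,
strictly — matching the strict comparisons used for the score thresholds. The
annotation (term → gene) and its universe are file inputs; no ontology
propagation is attempted, and the universe defaults to all annotated genes
(exposed as the annotation input itself, since the alternative — all measured
genes — is a caller decision).

The correlation screen reports, for every gene against a query gene, the
Pearson coefficient, a two-sided p-value from the exact t transform with
$S-2$ degrees of freedom (the parametric test is implied by the magnitudes
such screens report), and a BH column. Zero-variance genes are flagged and
excluded from the adjustment rather than silently dropped. The query itself
leads the output with statistic 1.

## HOMO–LUMO descriptors

DFT is *not* run here: quantum descriptor tables (compound, HOMO and LUMO
energies in eV, optionally a printed gap) are ingested from external
calculations. The packaged table carries the published B3LYP/6-31G* energies
of the seven licochalcones plus Glypallichalcone, Echinatin and
3,4,3′,4′-Tetrahydroxy-2-methoxychalcone. The gap is
$E_\mathrm{LUMO} - E_\mathrm{HOMO}$, reported to 2 decimals; the validator
flags rows whose printed gap disagrees with the recomputed one beyond a
tolerance (default 0.005 eV — exact at two printed decimals). On the packaged
table exactly two rows flag (LCD and Glypallichalcone, each off by 0.01 eV,
presumably because the source computed gaps before rounding the orbital
energies); the validator only reports, it never "corrects". Reactivity
ranking is ascending in the recomputed gap — a smaller gap read as easier
orbital excitation — placing LCG first and Glypallichalcone last.

## The synthetic-data module

Every input class has a generator with planted ground truth, so the whole
pipeline is testable offline: fingerprint libraries built from cluster
prototypes (each bit on with probability ρ = 0.02 of B = 2048) whose members
flip bits independently (ε = 0.01 by default), with background compounds as
fresh prototypes so their bit density matches the families; per-compound
target sets (7 × 25 genes) sharing an exactly-17-gene core inside a 2000-gene
universe, with scored disease tables and three-method DE tables that recover
the planted genes under the default filters; a PPI graph with a planted
6-clique over 100 proteins plus 1% Erdős–Rényi noise; annotation tables with
one planted term enriched 5-fold over expectation (term size 80 at the
default universe, chosen so the planted excess clears the 0.01 cutoffs with
room); and an expression matrix whose planted genes are bivariate-normal
correlated with the query at ρ = 0.6 across 50 samples.

One global seed expands into fixed per-stream child seeds (compounds, genes,
graph, expression, annotation), so adding a stream never perturbs another,
and identical configurations write byte-identical bundles. What the
generators do *not* emulate: real fingerprints are correlated through shared
substructure rather than independent bits; real target sets overlap through
pathway structure rather than uniform sampling; real PPI graphs are
scale-free rather than clique-plus-noise. Passing recovery tests therefore
demonstrates correctness of the algorithms under their stated assumptions,
not performance on real retrievals.

## Problem sizes and numerical choices

The test-suite simulations use the default shapes above (70-compound
libraries, 100-node graphs, 50 × 200 expression matrices), with 100–200
Monte-Carlo seeds for the recovery rates; these sizes make the planted
structure statistically unambiguous while keeping a full run of the suite in
the minutes range. Tolerances: oracle-equivalence checks are exact (integer
or 1e-12); Monte-Carlo rates assert the documented bounds (e.g. planted
clique on top in ≥ 95% of seeds). Ties anywhere (hub ranks, representatives,
reactivity) break lexicographically so reports are reproducible. Degenerate
inputs fail loudly: empty fingerprint pairs, n < 2 networks, n < 3
embeddings, k outside its range, inconsistent hypergeometric counts,
E_HOMO ≥ E_LUMO.

## A worked example

```{r example, eval = FALSE}
cmp <- licorice_compounds()
fps <- library_fingerprints(cmp, nbits = 2048)
s <- similarity_matrix(fps)
emb <- embed_2d(library_fingerprints(cmp, nbits = 1024), seed = 1)
net <- build_csn(emb, s)          # theta = D_max / 24
cl <- cluster_csn(net, s)
head(cl$report)

d <- licorice_descriptors()
reactivity_ranking(d)[, c("compound", "gap_computed", "rank")]
```

## Known limitations

* Fingerprint bits are not interchangeable with other toolkits' (kekulized
  bond orders, no stereochemistry, own hash); only within-library comparisons
  are meaningful.
* The CSN threshold rule needs library-scale inputs; a handful of compounds
  will embed as singletons.
* Published per-compound closeness values from a study's full library cannot
  be reproduced from a printed excerpt plus an unknown embedding seed; the
  package reproduces the *procedure* and its determinism, not those numbers.
* Gene symbols are matched as strings; no alias mapping.
* The enrichment stage consumes flat term annotations; GO ancestry and
  pathway topology are out of scope.
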