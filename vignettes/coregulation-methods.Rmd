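---
title: "Inferring a co-regulatory network by minimum-weight V-shape selection"
author: "vshapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a co-regulatory network by minimum-weight V-shape selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vshapes)
```

## The problem

An affinity transcriptional regulatory network records every statistically
significant predicted binding of a transcription factor (TF) family to the
promoter region of an operon. It is deliberately an over-representation of
the regulation that actually occurs in the cell: motif scans produce false
positives, and a TF that *can* bind a promoter need not use that binding
under any given condition. `vshapes` implements a parsimony method that
extracts from such a network the sub-network most likely to *co-regulate*
a set of metabolic pathways: bacterial operons that belong to the same
pathway must be co-expressed, so arcs that help connect same-pathway
operons to a common regulator — directly or through regulatory cascades —
are retained, and all others are discarded. The motivating application is
the bioleaching bacterium *Acidithiobacillus thiooxidans*, whose
sulfur-oxidation, energy and biosynthesis pathways are the six default
pathway categories, but every stage is generic.

The package covers the whole path from genome to topology report:

1. **Operons and promoters** from gene coordinates (`callOperons()`,
   `extractPromoters()`).
2. **Motif scanning with exact p-values** (`buildScoreModel()`,
   `scanPromoter()`), a reimplementation of the standard FIMO-style scan.
3. **Affinity network assembly** with TF-family collapsing
   (`buildAffinityNetwork()`).
4. **Co-regulatory arc selection** by minimum-weight V-shapes
   (`assignWeights()`, `minWeightVShape()`, `selectCoregulatoryArcs()`,
   `filterAndAssemble()`).
5. **Topology analysis** (`topologyReport()` and its parts).
6. **Synthetic data with planted ground truth** (`generateGenome()`,
   `plantMotifs()`, `plantNetwork()`, `plantCoregNetwork()`), so every
   stage is testable end to end without external data.

## Operons and promoter regions

An operon is a maximal run of consecutive genes on the same strand of one
contig in which every intergenic gap is **strictly less than 50 bp**
(`operonMaxGap`); the gap between two genes is
`start(next) − end(prev) − 1`, the number of bases strictly between the
coding sequences. Any intergenic region **strictly longer than 50 bp** is
a putative promoter region. Three decisions close the gaps these two
rules leave open:

* A gap of exactly 50 bp splits the operon *and* is not a promoter; such
  regions are retained in the output with no downstream operon, so they
  can be audited.
* Overlapping same-strand genes (negative gap) are merged — the gap is
  trivially below the threshold.
* A contig-end flank longer than 50 bp upstream of the first (on `+`) or
  last (on `-`) operon is treated as a promoter and flagged
  `contig_end`; on draft genomes, discarding those flanks would
  silently remove real promoters.

A promoter belongs to each flanking operon whose 5′-most gene abuts it,
so a region between divergently transcribed operons serves both, one
between convergent operons serves neither, and promoters are never
truncated to a fixed window — the whole intergenic region is scanned.

## Exact match p-values

Each TF family's PSSM (columns summing to 1) is turned into an integer
score model: entry `round(s · log2((p + κ·b) / ((1+κ)·b)))` with
pseudocount `κ = 0.01`, background `b` (uniform by default) and scale
`s = 1000` (FIMO-like granularity; configurable). Because positions are
independent under the 0-order background, the null distribution of the
total integer score of a random sequence is the convolution of the
per-position score distributions, computed exactly by dynamic programming.
`scorePvalue()` is then a table lookup: `P(score ≥ x)` for every
achievable score, with `p = 1` at the minimum and `p = 0` above the
maximum. The test suite checks this table against full `4^w` enumeration
for widths up to 6.

Both strands are scanned at every offset; an occurrence is a match iff
its p-value is **at or below** the threshold (a p-value exactly equal to
the threshold matches). Ambiguous bases score as the rounded
background-expected column score, which keeps the DP exact for ACGT
sequence and degrades gracefully otherwise. No multiple-testing
correction is applied across offsets: the method thresholds
per-occurrence p-values, as FIMO does by default.

Two thresholds coexist deliberately. The scan keeps occurrences at
`p ≤ 1e-4` and flags those at `p ≤ 1e-5` as confident; the final network
filter removes arcs with `p > 9e-5`. The stricter constant is the
published affinity criterion, yet selected arcs are reported up to
`p < 1e-4`; the two are reconcilable only if the scan itself was looser,
so both are separate configuration fields (`scanPThreshold`,
`confidentPThreshold`, `finalArcPThreshold`) rather than a guess at a
single intended value.

## The affinity network

Nodes are TF *families* (one node per family, however many genes encode
it) and operons. An arc `F → O` means family F has at least one match in
a promoter of operon O and carries the minimum p over those matches; when
O contains a gene coding for a TF of family G the arc becomes the
family-to-family arc `F → G`. Operons are therefore sinks unless they
code for TFs, which is what makes the apex of every V-shape a TF node.

## Minimum-weight V-shapes

Arcs are ranked by p-value and split into four equal groups (stable sort;
a remainder of `r` goes to the `r` lowest-p groups), which receive
weights 1, 2, 4, 8 — low p, low weight. A **V-shape** for two operons
`(a, b)` is the union of two directed paths from a common apex `C` ending
at `a` and `b` and sharing no node other than `C`; its weight is the sum
of its arc weights, so minimum-weight V-shapes simultaneously prefer few
arcs and confident arcs.

For a fixed apex, the optimum is a 2-unit minimum-cost flow on the
node-split transformation (every node except the apex has capacity 1),
which enforces node-disjointness exactly; the global optimum is the
minimum over candidate apexes (TF nodes with out-degree ≥ 2, a necessary
condition). "All arcs in some minimum-weight V-shape" is decided per arc
by re-optimising with that arc forced into the solution via the standard
lower-bound reduction (a unit of demand across the arc's endpoints routed
through a super source and sink). This keeps all edge costs non-negative
— important because the network may contain cycles, where the usual
cost-subtraction trick for forcing an arc can create negative cycles and
break the solver. Explicit enumeration of all V-shapes can be
exponential, so it exists only as the exported test oracle
`enumerateVShapes()` for networks of ≤ 12 nodes; the oracle and the flow
solver are checked against each other on 100 random instances.

Selection iterates over all unordered same-category operon pairs, takes
the union of optimal-V-shape arcs, and records per-arc provenance
(`category:a|b` tokens). Weight quartiles are computed over the whole
affinity network, not only over arcs reachable in V-shapes — the
alternative is one flag away but is not the default, as nothing in the
method's description suggests a restricted ranking. Finally
`filterAndAssemble()` removes arcs with original `p > 9e-5` (retaining
`p = 9e-5` exactly), replaces TF-coding operons by family nodes, merges
the parallel arcs that collapse creates (keeping the minimum p and the
union of provenance), and drops isolated nodes.

## Topology analysis

* **Cycles**: complete Johnson-style enumeration — for each start node,
  depth-first search restricted to the strongly connected component of
  the subgraph on nodes not smaller than the start, so acyclic regions
  are never explored. A cap (default 10,000) aborts on far-from-acyclic
  inputs.
* **Minimum feedback arc sets**: exact minimum hitting set over the
  enumerated cycles by branch and bound, returning *all* optima (up to
  1,000, with a truncation flag).
* **Levels**: longest-path layering after removing a chosen feedback arc
  set; sources are level 1 and every remaining arc strictly increases
  the level. The level count is reported per feedback-arc choice, since
  it genuinely depends on the choice; no single count is asserted.
* **Tree distance** of the TF-TF subgraph: how many arcs must be removed
  to leave a tree. The default `"undirected"` mode removes the cycle
  rank `m − n + c` of the underlying undirected multigraph. This is the
  sense consistent with a network that has several in-degree-0 primary
  regulators: a directed branching can keep at most `n − (number of
  roots)` arcs, so with 8 primaries among 34 TFs a 33-arc "tree" is
  only possible undirected. The `"branching"` mode (maximum branching
  via Edmonds' algorithm, unit weights) is provided as the directed
  alternative and is oracle-tested.
* **Primary regulators**: TF nodes with in-degree 0.
* **Reachability table**: operons of each category reachable from each
  regulator by directed paths (direct binding or cascades); categories
  ascending by size, regulators descending by total, TOTAL row of column
  sums.
* **Exclusivity table**: an operon counts for primary P iff P is the
  *only* primary that reaches it; percentages are rounded half-up to
  integers and formatted `n (p%)`.
* **Minimal controlling sets**: smallest candidate-regulator subsets
  whose reachable sets jointly cover a category, by exhaustive search in
  increasing cardinality (candidates are the primaries by default, all
  TFs on request — both readings of "minimum sets of transcription
  factors" are available), with a uniqueness flag.

## Synthetic data and what it does (not) show

The generators define the package's study conditions:

* `generateGenome()`: intra-operon gaps uniform on 1–49 bp, inter-operon
  gaps uniform on 60–500 bp, gene lengths 300–900 bp, i.i.d. background
  sequence. These distributions are explicit arguments — the defaults are
  arbitrary but fixed, chosen so the true operon partition is
  recoverable by construction.
* `plantMotifs()`: sites are sampled from the emitting PSSM, verified to
  pass the scan threshold under the exact score model (up to 100
  redraws), and written into real promoter sequence on a random strand
  at a non-overlapping offset. `randomPssm()` defaults to 0.91 consensus
  probability, ≈ 1.4 bits per position, so a width-10 motif exceeds 10
  bits.
* `plantNetwork()`: a TF hierarchy with designated in-degree-0
  primaries; back-arcs added one at a time and verified by cycle
  enumeration to create exactly the requested number of cycles; each
  category's operons regulated directly by a category apex TF ("signal"
  arcs, p log-uniform on [1e-8, 1e-5]); "decoy" arcs (p log-uniform on
  (1e-5, 1e-4]) from TFs other than the target's category apex. Because
  a signal arc always has the lowest p — hence a weight no larger than
  any other in-arc of its operon — the apex V-shape meets the weight
  lower bound for every same-category pair, and no decoy can appear in a
  minimum-weight V-shape. Recovery of 100% signal / 0% decoy is
  therefore the *expected* outcome, and the acceptance thresholds (≥ 90%
  / ≤ 10%) guard the implementation, not a statistical margin.
* `plantCoregNetwork()` builds a co-regulatory network with an exact
  composition (node and arc counts per kind, primaries, connected TF-TF
  subgraph), used to exercise the count identities and the tree-distance
  arithmetic at the composition reported for the reference organism.

Passing these closed-loop tests shows the algorithms are implemented
correctly under their own assumptions. It does **not** show performance
on real genomes: real intergenic distances are not uniform, real operons
are condition-dependent, real motifs are dirtier than sampled consensus
sites, real backgrounds have composition bias, and real co-regulation is
not generated by single category apexes. The genome-scale inputs of the
reference organism (annotation, TF list, PSSMs) are not publicly
deposited, so the genome-scale network figures are not recomputable here;
what is recomputed are the exact algorithmic components and the published
arithmetic identities.

## Numerical choices and degenerate inputs

* Integer score scale 1000; DP probabilities are exact double arithmetic,
  no approximation beyond the integer rounding of scores.
* Ties in weight assignment: stable sort by (p, input order).
* Ties in maxima (hubs) flag all tied nodes.
* Percentages round half-up (away from even), one decimal for the tree
  distance, integers for exclusivity.
* Empty inputs: empty motif file → empty list with a warning; all arcs
  above the final threshold → empty network with a warning; empty TF
  subgraph → tree distance (0, 0.0); a category not coverable by the
  candidates → `feasible = FALSE`, not an error.
* Problem sizes in the tests (genomes of 20–40 genes, networks of ≤ 10
  TFs, oracle instances of ≤ 8 nodes, 20-seed recovery loops) were
  chosen so the exhaustive oracles stay exact and the whole suite runs
  in well under a minute per file.

## Known limitations

* The affinity model is binding affinity, not condition-specific
  regulation; only expression data could confirm an arc.
* Promoter scanning uses a 0-order background and no q-values.
* All-optima enumerations (feedback arc sets, controlling sets) are
  capped with explicit counts when the caps are hit.
* `minimalControllingSets()` is exhaustive and limited to ≤ 20
  candidates; that covers primary regulators comfortably but not
  arbitrary candidate sets.
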