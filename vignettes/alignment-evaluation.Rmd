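---
title: "Scoring, comparing and unifying PPI network alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, comparing and unifying PPI network alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netalignr)
```

## The problem

Protein–protein interaction (PPI) networks of different species can be
compared by *global network alignment*: an injective partial mapping
$f : V_1 \to V_2$ from the nodes of the smaller network $G_1 = (V_1, E_1)$
into the larger one $G_2 = (V_2, E_2)$. Many aligners exist, they optimize
different objectives, and there is no consensus on how to judge their
output. This package implements the evaluation side of that problem: it
scores alignments, compares and ranks aligners, measures how differently
alignments use the larger network, and exploits that diversity by taking
the union of several alignments into a single many-to-many mapping.

Throughout, "smaller" and "larger" are decided by node count (ties by edge
count, then by name; see `order_network_pair()`), because every score is
anchored to the smaller network. Node identifiers are case-sensitive,
whitespace-trimmed strings, matching the conventions of gene-symbol
catalogues where case is meaningful.

## The nine quality scores

Let $c$ be the number of *conserved edges*, i.e. edges $(u,v) \in E_1$ with
$(f(u), f(v)) \in E_2$, and let $i$ be the number of $E_2$ edges induced by
the image $f(V_1)$ (both computed by `conserved_subgraph()`).

* **NC** $= |f| / |V_1|$: node coverage.
* **EC** $= c / |E_1|$: edge correctness, the smaller network's view.
* **ICS** $= c / i$: induced conserved sub-structure, the larger network's
  view, penalizing alignments that map sparse regions onto dense ones.
* **S³** $= c / (|E_1| + i - c)$: the symmetric compromise; algebraically
  $S^3 = 1/(1/\mathrm{EC} + 1/\mathrm{ICS} - 1)$ wherever both are defined,
  so $S^3 \le \min(\mathrm{EC}, \mathrm{ICS})$.
* **LCC**: the node count of the largest connected component of the
  conserved subgraph (aligned source nodes joined by conserved edges). The
  raw size is exposed (`largest_conserved_component_size()`, which also
  reports the component's edge count as an alternative measure), but the
  score is normalized by $|V_1|$ so that it lies in $[0,1]$ and can be
  averaged across network pairs and correlated with the other scores. The
  component is built on the source side; its image is isomorphic, so the
  side does not affect the value.
* **KP, GO-BP, GO-MF, GO-CC** (`annotation_overlap_score()`): two aligned
  proteins are functionally similar if they share at least one annotation
  term (a KEGG pathway, or a GO term within one aspect). The score divides
  the number of functionally similar aligned pairs by
  $\min(a_1, a_2)$, where $a_k$ is the number of annotated proteins that are
  nodes of network $k$. Pairs with an unannotated member count zero in the
  numerator but are *not* excluded from the denominator — the denominator is
  a property of the networks' annotation coverage, not of the alignment.
  Terms are compared by exact identity; no ontology-graph propagation or
  semantic similarity is performed.

Undefined scores (an empty denominator, e.g. ICS when the image induces no
edges) are returned as `NA` with a warning, never as 0: conflating "no
induced edges" with "no conservation" would bias averages and correlations.

```{r scores}
g1 <- ppi_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")), "G1")
g2 <- ppi_network(c("x", "y", "z"),
                  rbind(c("x", "y"), c("y", "z"), c("x", "z")), "G2")
f  <- ppi_alignment(rbind(c("a", "x"), c("b", "y"), c("c", "z")), "G1", "G2")
topo_scores(g1, g2, f)  # a path aligned onto a triangle: EC 1, ICS 2/3
```

## Comparing aligners

Most aligners expose a balancing parameter $\alpha \in [0,1]$ interpolating
between topology-only and sequence-only guidance, typically swept in steps
of 0.1. For one aligner and one metric, `best_mean_score()` averages the
metric over network pairs at each $\alpha$ and keeps the best average (ties
to the smallest $\alpha$): an aligner is judged by its best
parameterization per metric. `tradeoff_score()` combines topological and
biological quality as $\sqrt{S^3 \cdot \mathrm{KP}}$.

Ranking uses *competition ranking* (`competition_rank()`): tied aligners
share the minimal rank, and the next distinct value's rank is one plus the
number of strictly better aligners (the "1, 1, 1, 4" pattern). The dense
"1, 1, 1, 2" alternative would be inconsistent with how three aligners tied
at NC = 100% are followed by rank 4. `aggregate_ranks()` averages each
aligner's ranks over all metrics (`avg_all`) and over the S³ and KP columns
only (`avg_s3_kp`); the default table ordering is by `avg_s3_kp` with
`avg_all` breaking ties — the ordering used when both averages are reported
side by side — and `sort_by = "avg_all"` switches to the overall average.
`score_correlation()` relates the nine metrics across all scored alignments
by Pearson correlation over pairwise-complete observations, so one missing
score does not discard a whole alignment; zero-variance metrics are flagged
and returned as `NA`.

## Agreement and unification

On the larger network, let $S_i$ be the target-side image of alignment $i$.
The *node mapping agreement* of two alignments is
$|S_i \cap S_j| / \min(|S_i|, |S_j|)$; the *exact mapping agreement* counts
source nodes mapped identically, normalized the same way (by the smaller
alignment), which keeps both statistics in $[0,1]$ and makes the exact
variant a lower bound on the node variant. Alignments produced with
source/target roles swapped are re-oriented with `orient_alignment()`
before comparison.

Low agreement between good alignments is an opportunity:
`unify_alignments()` takes the union of several one-to-one mappings into a
many-to-many `unified_mapping` that records, per (source, target) pair,
which alignments support it. `coverage_curve()` reports the fraction of a
chosen side covered by the union of the first $k$ alignments
($k = 0$ gives 0; the caller orders the alignments, best aligner first).
`soft_clusters()` groups smaller-network proteins mapped to the same larger
network protein — clusters are keyed by the target protein, may overlap,
and flatten back (`flatten_clusters()`) to exactly the unified pairs. The
choice of *which* alignments to unify (e.g. each aligner's best-S³ or
best-KP alignment) belongs to the caller; unification itself is
score-agnostic. No consensus one-to-one alignment is derived: the
many-to-many structure is the point.

## Enrichment and annotation transfer

Cluster coherence is tested by sampling without replacement:
`hypergeom_upper_tail(k, K, n, N)` is $P(X \ge k)$ for a hypergeometric
draw of $n$ from a universe of $N$ proteins of which $K$ carry the term
(delegated to `stats::phyper`, which is log-space stable), and
`bh_adjust()` is the Benjamini–Hochberg step-up (delegated to
`stats::p.adjust`). `cluster_enrichment()` tests, for every cluster with at
least two annotated members, every term carried by at least one member, and
reports the fraction of such clusters with at least one term significant
after correction.

Two design points were genuinely open and are configurable:

* **Background universe.** Default: the annotated proteins among the source
  network's nodes (clusters are subsets of that interactome). Any protein
  vector can be passed as `universe`.
* **BH family.** Default `"cluster"`: correction within each cluster's term
  family, matching the per-cluster question "does at least one term
  survive?". `"global"` pools all (cluster, term) tests into one family.

Only terms present in a cluster are tested (testing absent terms is vacuous
and inflates the family size), and unannotated members are ignored entirely
— they carry no information under sampling from the annotated universe.

`transfer_consistency()` asks the converse question: over clusters whose
target protein is annotated, how often does the union of the members'
annotations share a term with the target's? That fraction is how often
annotations could validly be transferred through the mapping.

## The synthetic generator

Real PPI networks and third-party alignment collections are large and
external; the generator provides controlled stand-ins so that every
operation is testable end to end.

* `make_network_pair()` builds $G_1$ as an Erdős–Rényi graph
  ($n_1 = 60$, edge probability 0.08 by default, i.e. mean degree ≈ 4.7,
  sparse like curated interactomes) and, under the default duplication
  model, builds $G_2$ ($n_2 = 90$) from a relabeled copy of $G_1$ by
  attaching the extra nodes preferentially by degree (2 edges each) and
  rewiring 10% of the edges. The planted alignment maps every $G_1$ node to
  its copy. The duplication model is the default because it produces pairs
  with genuine conserved structure — under no rewiring the planted
  alignment scores EC = ICS = S³ = 1 exactly, since every attachment edge
  touches a node outside the image. Independent Erdős–Rényi pairs are
  retained as a null model.
* `corrupt_alignment()` re-targets a chosen fraction of the planted pairs
  to targets drawn without replacement from the pool not used by the
  untouched pairs, preserving injectivity. At fraction 1 the result behaves
  like a random injection (its exact agreement with the planted alignment
  is near, not exactly, zero, since a pair can draw its own target back).
* `make_annotations()` gives every protein one uniform term from a 50-term
  vocabulary (chance overlap ≈ 1/50) and adds a shared term to each planted
  pair with probability `coherence` (default 0.8, a strong but imperfect
  functional signal). The planted KP score is therefore ≈ coherence and
  decreases towards the chance baseline as mappings are shuffled.

All generators run under a caller-supplied integer seed, restore the
caller's RNG state, and are byte-reproducible. What the fixtures do *not*
emulate: scale-free degree heterogeneity beyond mild preferential
attachment, correlated annotation structure (GO term co-occurrence, term
hierarchies), incomplete annotation coverage, or the noise profile of
interaction-detection technologies. Tests passing on these fixtures
demonstrate correctness of the computations and the expected qualitative
behaviour (scores track planted signal; unions cover more than single
alignments), not quantitative claims about real interactomes.

## Numerical and edge-case conventions

* Self-loops and duplicate edges are dropped on input with counted
  warnings; homodimer interactions have no defined role in these scores.
* Parsers raise errors naming the offending line or node (malformed lines,
  injectivity violations, unknown node references); *score* functions never
  raise for empty denominators but return `NA` with a warning.
* Edge lists cannot express isolated nodes; the LEDA `.gw` writer is
  provided for lossless round trips and is used by `write_synthetic_study()`.
* Rank ties: competition ranking as above; `best_mean_score()` ties resolve
  to the smallest $\alpha$ (reported results should prefer the cheaper,
  more topological parameterization only by convention — some fixed rule is
  needed for reproducibility).
* Problem sizes in the test suite and acceptance script (networks of 60–90
  nodes, 30–50 seeds per Monte-Carlo check, brute-force oracles on ≤ 12
  nodes) were chosen so the full suite completes in well under a minute
  while keeping Monte-Carlo comparisons stable to the asserted direction.

## Limitations

* Only evaluation and unification are implemented; no alignment search of
  any kind, and no graphlet or spectral node similarities.
* Annotation handling is deliberately flat: no GO DAG propagation, no
  semantic-similarity scores, no term-size filters.
* The enrichment defaults (background universe, BH family scope) cannot be
  validated against external data from within this package; both are
  exposed as arguments precisely because reasonable analysts may differ.
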