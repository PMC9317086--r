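---
title: "Two-stage supervised protein complex prediction: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage supervised protein complex prediction: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexpred)
```

# The problem and the model

A protein complex is a set of proteins that assemble into a functional
unit. In a protein–protein interaction (PPI) network, complexes tend to
appear as subgraphs that are (i) internally dense, (ii) well separated
from their surroundings, and (iii) functionally coherent — their members
share Gene Ontology (GO) annotations. `complexpred` exploits all three
signals in a two-stage supervised pipeline:

1. **weight** every edge by combining a topological similarity with a GO
   annotation-overlap similarity, discarding zero-confidence edges;
2. **detect** candidate subgraphs (SVCC stage): seed with maximal cliques,
   score subgraphs with a calibrated SVM over 16 topological features,
   greedily expand while the score improves, and resolve overlaps;
3. **classify** candidates with a random forest over averaged node-embedding
   vectors, keeping only those predicted to be genuine complexes.

The pipeline assumes an undirected simple graph of binary interactions
(no weights on input, no self-loops, no direction), a reference catalog
of complexes with at least 3 members for training, and optionally GO
annotations in GAF 2.x format.

## Edge weighting

For an edge $(v,u)$ the topological part is the high-order common-neighbor
score
$$HOCN(v,u) = \frac{JCS(v,u) + CNS(v,u) + |CN(v,u)|}{|CN(v,u)| + 1},$$
where $JCS$ is the Jaccard similarity of the neighbor sets and
$CNS(v,u) = \sum_{w \in CN(v,u)} JCS(v,w)\,JCS(w,u)$ measures how strongly
the shared neighborhood is tied to both endpoints. $HOCN$ is 0 exactly when
the edge has no common neighbors and its endpoints share no neighborhood
structure, and is always below 2.

The biological part is
$$sim(v,u) = |C(v,u)| \cdot \left(\log_{10} \frac{\min_i |S_i(v,u)|}{S_{max}}\right)^2 ,$$
driven by the number of shared GO terms and the specificity of the most
specific shared term. The final weight is $\sqrt{sim + HOCN}$.

Numerical choices here:

* **Log base.** Only rescales $sim$ globally; base 10 is the default and
  `log_base` is exposed. Results change only through the relative balance
  of $sim$ against $HOCN$ inside the square root.
* **Empty shared-term set.** Short-circuits to $sim = 0$ rather than
  evaluating the logarithm; proteins missing from the annotation index
  contribute 0 likewise.
* **Low-confidence filter.** `min_weight = 0` by default: only edges with
  exactly zero combined evidence drop. Any stricter threshold is a user
  decision (`--min-weight`).
* **Existing edges only.** Scores are computed for edges of the input
  network; the package does no link prediction.

## The 16 features

The feature vector of a candidate subgraph is frozen at 16 named entries:
5 from the unweighted view (density; max/mean/median degree; population
variance of the node clustering coefficient), 9 from the weighted view
(weighted density; max/mean/median weighted degree; mean and population
variance of internal edge weights; modularity; mean and max weighted
clustering coefficient), and 2 degree-related statistics (mean and
population variance, across nodes, of the mean degree of a node's
neighbors). This 5 + 9 + 2 breakdown, with density counted once per graph
view, is the package's canonical reading of "features from the weighted
and unweighted networks" summing to 16.

Conventions, all regression-tested against naive reimplementations:

* weighted density sums ordered pairs, so a unit-weight clique scores
  exactly 1;
* modularity is the only feature that sees the host network: it is
  $d_{in}/(d_{in}+d_{out})$ with $d_{in}$ the internal edge weight (each
  edge once) and $d_{out}$ the weight crossing the boundary — every other
  statistic is computed on the induced subgraph;
* the weighted clustering coefficient sums $w(v,j)+w(v,h)$ over adjacent
  neighbor pairs (triangles through $v$), each unordered pair once, and
  divides by $w(v)(k_v-1)$;
* variances are population variances; medians use the midpoint for even
  counts; neighbor-degree averages use unweighted induced degrees
  (the weighted alternative is a documented non-default);
* degenerate cases (degree < 2, no internal edges, zero weighted degree)
  map to 0, so vectors never contain NaN or Inf.

## Stage 1: SVCC

The subgraph scorer is a polynomial-kernel support vector classifier:
cost 3, degree 4, coef0 0, tolerance 0.001, probability calibration on.
Two implementation details matter for reproducing that configuration with
`e1071`:

* `gamma` follows the "scale" convention, $1/(16 \cdot Var(X))$ over the
  training feature matrix, computed explicitly;
* `scale = FALSE`: the features are used raw. `e1071`'s default internal
  standardization interacts badly with a degree-4 kernel anchored at
  coef0 = 0 (centered features make the kernel nearly flat), and the
  scale-style gamma already adapts to the feature variance.

Training data pair the reference complexes (label 1) with size-matched
random node sets (label 0) drawn uniformly without replacement; a draw
identical to a positive is rejected and redrawn. With a fixed seed the
draws, the SVM's internal calibration folds, and hence the fitted scorer
are fully reproducible.

Candidate detection then proceeds:

* **Seeding.** All maximal cliques with ≥ 3 nodes (Bron–Kerbosch via
  igraph), in deterministic canonical order, enumerated on the
  confidence-filtered weighted network.
* **Selection.** Rank seeds by probability; scanning down, remove a seed
  sharing strictly more than α = 2 members with a kept one. Strictness
  matters: sharing exactly 2 members is allowed, so size-3 cliques are not
  wiped out wholesale.
* **Expansion.** Repeatedly score $C \cup \{v\}$ for every external
  neighbor $v$ and add the best one if it strictly increases the
  probability (lexicographic tie-break). Neighbors are drawn from the same
  confidence-filtered network the seeds came from: expanding across
  edges that carry no evidence reintroduces exactly the noise the
  weighting removed, and measurably degrades planted-complex recovery.
* **Filtration.** Rank candidates by probability. The top candidate
  resolves every lower-ranked overlapping one: overlap ratio ≥ β = 0.8
  merges (union of members, rescored, re-ranked — merges do not cascade
  transitively beyond this reinsertion), overlap in (0, β) removes the
  lower-ranked candidate, disjoint candidates are untouched. Applying the
  removal rule only to overlapping pairs is deliberate: read literally, a
  "remove otherwise" rule would delete every disjoint candidate and leave
  a single prediction.

All ranking ties anywhere in the pipeline break by (probability, larger
size, lexicographic canonical member tuple), making every stage a total
order and the whole pipeline deterministic for a given seed.

## Stage 2: embedding and classification

Node vectors come from biased second-order random walks (return parameter
p = 8, in-out q = 1, 10 walks of length 80 per node) and skip-gram with
negative sampling (64 dimensions, window 10, 5 epochs, 5 negatives,
initial learning rate 0.025). The walk-bias defaults favor exploration
away from the previous node, which on modular graphs keeps walks inside
their community. Hyperparameters absent from the walk specification
(window, epochs, negatives) use conventional skip-gram defaults and are
configurable. The trainer is a single-threaded C++ routine with a private
RNG, so a seed reproduces the embedding bit for bit; walks default to the
unweighted topology (`use_weights` switches to weight-proportional steps).

A complex's vector is the coordinate-wise mean of its member vectors. The
classifier is a 1000-tree random forest on real-versus-random complex
vectors; candidates with positive-class probability above 0.5 (the
configurable decision threshold) survive as final predictions.

## Evaluation protocol

Matching uses neighborhood affinity
$NA(b,p) = |V_b \cap V_p|^2 / (|V_b||V_p|)$ with the strict threshold
$NA > 0.25$; $N_{cp}$ and $N_{cb}$ count matched predictions and matched
references, giving precision $N_{cp}/|P|$, recall $N_{cb}/|B|$ and their
harmonic mean. Enrichment p-values are upper-tail hypergeometric
probabilities, implemented as the explicit finite sum and cross-checked in
the tests against the survival function `phyper`; the universe defaults to
the network's node count, no multiple-testing correction is applied (an
optional Bonferroni flag would be trivial but raw per-complex values are
the convention this protocol follows), and unannotated aspects report
p = 1.

`crossValidate()` shuffles the catalog into 5 seeded folds; each fold's
models never see that fold's complexes, per-fold predictions overlapping
any training complex at ratio ≥ 0.9 are discarded, the pooled survivors
are deduplicated by ranked scan at strict overlap > 0.6 (exact duplicates
always collapse), and the result is evaluated against the full catalog.
The asymmetry (≥ 0.9 versus > 0.6) follows the protocol wording this
package implements. The node embedding is trained once per network and
shared across folds — it uses no complex labels, so no leakage, and it
saves a five-fold recomputation.

# The synthetic benchmark

`generateBenchmark()` emulates what the method assumes about real data:
an Erdős–Rényi background (300 nodes, edge probability 0.01 — mean degree
about 3, sparse like curated interactomes), 20 disjoint planted complexes
of 3–8 nodes wired internally at 0.9, and annotations in which 90% of
planted complexes share a dedicated GO term over all members while each
protein independently gains one random noise term at a per-protein rate of
0.05. Aspect letters cycle BP/MF/CC so aspect filtering is exercised.
These defaults are the package's fixed study conditions: small enough that
the full pipeline (and its five-fold cross-validation) runs in tens of
seconds, large and noisy enough that recovery is not trivial.

What the generator deliberately does **not** emulate: scale-free degree
distributions, overlapping complexes, correlated false-negative edges, and
annotation propagated up the GO graph. Passing the planted-recovery tests
therefore demonstrates that the machinery works under the stated
assumptions — not that real-interactome performance will match; on real
data the clique seeding in particular is sensitive to missing edges.

# Problem sizes and determinism in the tests

The unit suite checks every edge score and every feature against naive
per-definition oracles exhaustively on all graphs with up to 5 nodes, and
the acceptance suite extends the edge-score check to all 32,768 six-node
graphs against an independent matrix-algebra derivation. The
hypergeometric tail is compared with `phyper` for every configuration with
universe ≤ 30. Planted-recovery checks run the full two-stage pipeline on
the default benchmark across seeds 1–5; pipeline determinism is verified
by byte-comparing prediction files from repeated seeded runs on a
120-node benchmark. These sizes are the package's own test design: big
enough to be meaningful, small enough to keep the suite fast everywhere.

# Known limitations

* Clique seeding cannot recover a complex whose induced subgraph contains
  no triangle-or-larger clique after weighting; greedy expansion only
  partially compensates.
* The filtration rule that removes partially overlapping lower-ranked
  candidates is aggressive by construction; it trades recall for
  precision, and a candidate absorbed into the wrong neighbor during
  expansion can eliminate an otherwise correct prediction.
* Platt-style probability calibration on small training sets (tens of
  complexes) is noisy; rankings are stable but absolute probabilities
  near 0.5 should not be over-interpreted.
* GO-based weighting and GO-based enrichment share information: enrichment
  of predictions from a GO-weighted network is partly circular and should
  be read as a sanity check, not independent validation.
* Direct annotations only: terms are not propagated to ancestors before
  counting, so annotation granularity affects both weighting and
  enrichment.
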