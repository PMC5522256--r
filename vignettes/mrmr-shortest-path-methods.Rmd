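---
title: "Methods: mRMR feature selection with shortest-path network analysis"
author: "mrmrpath"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: mRMR feature selection with shortest-path network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Differential-expression screens of tumour versus non-tumour transcriptomes
return long lists of individually associated genes, many of which carry the
same signal. For biomarker panels a compact set of *mutually complementary*
genes is preferable: each member should add information the others do not
already carry. `mrmrpath` implements a pipeline built around that idea for
two-class expression studies (the motivating design is a pancreatic ductal
adenocarcinoma cohort of 45 tumour and 45 adjacent non-tumour samples):

1. rank probes by minimum-redundancy-maximum-relevance (mRMR);
2. pick a subset size by incremental feature selection (IFS) scored with
   jackknife-validated nearest-neighbour classification;
3. map the selected genes onto a confidence-filtered protein-protein
   interaction (PPI) network and extract the sub-network of pairwise
   shortest paths between the mapped seed proteins;
4. test each sub-network protein's path-occurrence betweenness against
   random seed sets with a permutation test.

## Models and procedures

### Mutual information

Relevance and redundancy are both quantified by mutual information (MI).
The population MI between continuous variables is an integral over the
joint density; it is only ever accessed through estimators:

* **correlation estimator** (default): \(\hat I = -\tfrac12\ln(1-\hat\rho^2)\)
  with \(\hat\rho\) the Pearson correlation (point-biserial against the binary
  phenotype). Exact for bivariate Gaussians and the estimator used by the
  standard continuous mRMR implementations in R. \(\hat\rho^2\) is clipped at
  \(1-10^{-12}\), so the MI of a variable with itself is the finite cap
  \(\tfrac12\ln 10^{12}\approx 13.8\) nats rather than infinity.
* **binned estimator** (sensitivity check): three equal-frequency bins per
  continuous variable, plug-in MI of the contingency table. Binary inputs
  pass through unbinned.

Zero-variance probes get MI 0 (with a warning at the single-vector level):
a flat probe carries no information, and this convention makes it rank last
rather than crash the run.

### Greedy mRMR ranking

The first feature is the relevance maximum \(\arg\max_j I(x_j, y)\). Each
later step adds the feature maximizing

\[ q \;=\; I(x_j, y) \;-\; \frac{1}{|S|}\sum_{x_k \in S} I(x_j, x_k), \]

with \(S\) the already-selected set; the stored score of the first feature is
its relevance. Ranking stops at \(N\) features (default 500, capped at the
probe count). Scores within \(10^{-9}\) of the step maximum are treated as
tied and resolved by input probe order; without the tolerance, two probes
with mathematically identical scores (common under the binned estimator)
could be ordered by floating-point accumulation noise, and the ranking
would not be reproducible against an independent re-evaluation of the same
criterion.

### IFS with jackknife nearest-neighbour classification

Subset \(s_i\) is the first \(i\) ranked features (so subsets are nested by
construction). Each subset is scored by leave-one-out (jackknife)
\(k\)-nearest-neighbour classification; \(k=1\) by default, since the
cosine-distance nearest-neighbour line of work this follows is
parameter-free at \(k=1\) and the source procedure states no \(k\). The
distance between two samples' selected-feature vectors is the Chou
cosine-type distance

\[ D(e_1, e_2) = 1 - \frac{e_1\cdot e_2}{|e_1|\,|e_2|} \in [0, 2], \]

symmetric and invariant to positive rescaling of either sample. Accuracy is
\((TP+TN)/(TP+TN+FP+FN)\) with tumour as the positive class. Distance ties
resolve by training-sample order and split votes by the single nearest
neighbour, making every prediction deterministic.

With one feature the cosine distance degenerates to sign agreement — a
property worth knowing when reading the low end of an IFS curve.

The selected size is the smallest \(i\) with accuracy within \(\delta\)
(default 0.01) of the curve maximum. This formalizes the parsimony argument
of choosing a compact panel whose accuracy is within a hair of the best
achievable (the motivating study preferred 10 probes at 0.88 over 80 probes
at 0.89); \(\delta=0\) reduces to the smallest argmax.

Expression values are used as loaded (log-scale microarray-like
intensities). The distance is scale-invariant per sample but not per
feature; an optional per-feature z-score switch (`standardize = TRUE`) is
provided, off by default because the source procedure describes no
normalization.

### PPI sub-network of shortest paths

Edges with combined confidence **strictly greater than** 0.8 form the
high-confidence network (on STRING's 0–1000 integer dialect that is > 800;
the reader auto-detects the dialect by any score above 1). Selected genes
are expanded through a gene-to-protein multimap and intersected with the
network's nodes — the mapped/unmapped counts at each stage are logged,
mirroring the funnel a real study reports (10 probes → 9 genes → 27
proteins → 8 in network).

For every unordered seed pair one minimal-hop path is stored. With unit
edge weights Dijkstra's algorithm reduces to breadth-first search, which is
the implementation (a `weighting = 1 - score` variant was considered and
rejected for the default because the graph is already confidence-filtered
and the source procedure speaks only of shortest paths on the filtered
network). Among co-minimal paths the lexicographically smallest node
sequence is chosen, oriented from the lexicographically smaller endpoint:
walking the BFS distance gradient and taking the smallest-named admissible
neighbour at each step yields exactly that path. Determinism here is what
makes path-level results testable; enumerating all co-minimal paths was
deliberately left out (see Limitations). Unreachable pairs are recorded as
no-path and skipped.

A protein's **betweenness** is the number of stored paths on which it lies
as a non-endpoint node — path occurrence between seeds, not global
betweenness centrality. Seeds can accumulate betweenness through paths
between other pairs. Since each unordered pair contributes at most one
path, the counts satisfy \(\sum_v b_v = \sum_{\text{paths}} (\text{path
length} - 1)\) in nodes, an identity the tests assert.

### Permutation test for hubs

Each of `n_permutations` (default 1000) rounds draws `seed_set_size`
(default 8) nodes uniformly without replacement from the whole filtered
network, recomputes the path set under identical rules, and counts each
target protein's betweenness. The per-protein p-value is
\((c+1)/(n+1)\), where \(c\) counts permutations with betweenness at least
the observed value; the +1 correction avoids p = 0 and is standard
permutation practice, while the uncorrected proportion is reported
alongside for transparency. Significance is p < alpha (default 0.05), with
no multiple-testing correction — deliberately matching the source
procedure, which applies none. Random seeds are drawn uniformly rather than
degree-matched because nothing stronger than "randomly selected" is
specified; a degree-matched null would be stricter and is out of scope.

## The synthetic-data generator

Real cohort and interaction data require external downloads, so the
package ships simulators whose defaults define the study conditions used
throughout the tests:

* **Expression**: 45 samples per class; 10 *informative* probes
  \(N(\pm d/2, 1)\) by class with effect size \(d = 1\) (one within-class SD —
  moderate differential expression, chosen so that single probes classify
  imperfectly and the IFS curve keeps rising over roughly the first dozen
  features, the regime the motivating study's curve shows); 10 *redundant*
  probes, each a randomly chosen informative probe plus \(N(0, 0.1)\) noise
  (correlation with the source about 0.995, making the mRMR-versus-relevance
  contrast sharp); 480 *noise* probes \(N(0,1)\). Probe order is shuffled.
* **Network**: 200-node preferential-attachment background (PPI degree
  distributions are heavy-tailed; the exact topology is not load-bearing),
  3 edges per new node, one planted hub wired to 30 random nodes, edge
  confidences uniform on [0.85, 1] so the 0.8 filter keeps the simulated
  graph intact and connected.

What the generator does **not** emulate: probe-level microarray noise
models, batch effects, correlated noise blocks, annotation errors, or the
realistic mixture of weak and strong effect sizes. Passing tests therefore
demonstrate that the algorithms do what they claim on data with known
ground truth — not that the pipeline will reach any particular accuracy on
a real cohort.

### A deliberate subtlety: clone displacement

The redundant copies are statistically exchangeable with their sources
(sd-0.1 clones). mRMR will keep exactly one representative of each such
pair and demote the other — that is its defining behaviour. *Which* twin
survives depends on whose estimated relevance is larger, and the clone's
expected deficit (≈ 0.003 in correlation) is smaller than the sampling
noise of a correlation at n = 90 (≈ 0.01). Roughly 40% of copied sources
are therefore displaced by their own clones in any one dataset. Every
planted *signal* is recovered (source or clone) in essentially every run,
but the count of role-labelled "informative" probes in the selected subset
fluctuates around 6–10 of 10. Both quantities are reported by
`scripts/acceptance.R` (`informative_probes_in_subset` and
`planted_signals_recovered`); only the signal-level count is stable by
construction.

## Numerical and degenerate-input choices

* MI tie tolerance \(10^{-9}\) in the greedy step (above).
* Chou distance is clamped to [0, 2] against floating-point excursions;
  zero-norm sample vectors are a hard error naming the vector.
* Duplicate unordered PPI edges collapse to the maximum score; self-loops
  are dropped; reading a file the package wrote changes nothing.
* Probe rows with any missing or non-numeric cell are dropped at load time
  with a count (the simplest defensible policy; imputation is out of scope).
* Jackknife rounds shrink `k` to the available training size; a two-sample
  dataset with one sample per class is validly scored (accuracy 0).
* All randomness flows from explicit seeds: simulator specs carry their
  own, and the pipeline derives its permutation seed from the global seed
  by a fixed offset so stages rerun alone reproduce their outputs.

## Problem sizes

The test suite and acceptance script run the full study design (500 probes
× 90 samples, 500-point IFS curve, 1000-permutation hub test on a ~200-node
network) plus many miniature property checks (graphs of ≤ 12 nodes against
brute-force oracles, 50 random datasets against an independent greedy
re-evaluation). These sizes were chosen to exercise every code path at the
motivating study's sample design while keeping a complete run in minutes on
a laptop core.

## Known limitations

* One path per seed pair: a protein lying only on co-minimal alternatives
  to the stored path receives no betweenness. The motivating study's
  "betweenness 14 = at least 7 paths" remark suggests it may have counted
  both orientations or multiple co-minimal paths; this package counts each
  unordered pair once and documents the divergence rather than guessing.
* The published headline numbers (accuracy 0.88/0.89, 40 sub-network
  proteins, MAPK1 betweenness 14) depend on a specific GEO series and
  STRING release and are not reproduced at desk scale; the pipeline's
  correctness is established property-wise instead.
* The correlation MI estimator sees only linear dependence; the binned
  estimator is offered for sensitivity analysis, not as a calibrated
  alternative.
* No multiple-testing correction in the permutation stage (by design, see
  above); interpret the significant-hub count accordingly.
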