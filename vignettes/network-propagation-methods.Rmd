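---
title: "Methods: supervised network propagation for drug-disease association"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rwrdr` scores drug-disease pairs by how similarly the two entities diffuse
over a protein-protein interaction (PPI) network. The network is an
undirected simple graph over gene identifiers; analyses run on its largest
connected component, whose binary adjacency matrix $A$ is normalized column
by column,

$$A'_{ij} = \frac{A_{ij}}{\sum_k A_{kj}},$$

so that $A'$ is column-stochastic and one step of the walk redistributes a
node's probability evenly over its neighbors. Each entity is represented by
a seed distribution $P_0$ over the network's genes, and the random walk
with restart

$$P_{t+1} = (1 - r)\,A' P_t + r P_0$$

is iterated until $\lVert P_{t+1} - P_t\rVert_1 < \text{tol}$. The restart
probability $r$ keeps a fraction of the probability mass anchored near the
seeds; the fixed point (the *stationary profile*) is a smoothed,
network-aware signature of the entity. A disease-drug pair is scored by
the sample Pearson correlation of the two stationary profiles over **all**
network nodes, and pairs are ranked by that score.

The supervised element is *seed augmentation*. For a disease $d$, the
direct seed is the normalized indicator of its own genes; if drugs
$g_1,\dots,g_m$ are known to treat $d$, their target-set indicator vectors
are summed **with multiplicity** (a gene targeted by $k$ of the drugs
contributes $k$), normalized, and mixed into the final seed

$$P_d = t\,P_{\text{direct}} + (1 - t)\,P_{\text{partners}},$$

with $t = 0.5$. Drugs are treated symmetrically, mixing in the gene sets of
the diseases they treat. Retaining multiplicity (rather than taking a set
union) follows from reading the partner aggregation as an arithmetic sum of
indicator vectors: a gene supported by several independent associations is
better evidence of relevance than a gene supported by one.

## Evaluation protocol

`independent_validation()` is the unsupervised baseline: direct seeds only,
one global Mann-Whitney AUC with known pairs as positives and all other
disease-drug pairs as negatives.

`run_cv()` is the supervised protocol: the association table is split
uniformly at random into $k$ folds (sizes differing by at most one),
re-randomized on each of `repeats` repeats. For each fold, seeds are
augmented using the training folds only; the fold AUC takes the held-out
pairs as positives and all never-known pairs as negatives, with training
positives excluded from the ranked pool. Ties contribute 0.5. Since the
training pairs never enter the test fold's seed construction, fold-masked
seeds are bit-identical to seeds built from an association table with the
fold physically deleted — the no-leakage property the test suite checks.

Several choices here are deliberately conservative where the protocol is
underdetermined:

* **Negative set / ranking scope.** One global ranking over all
  disease-drug pairs per fold, rather than per-disease ranking, is the
  simplest reading that yields one AUC per fold. Per-disease AUCs (used for
  class-level summaries via `auc_by_class()`) rank only that disease's row
  against its own never-known drugs.
* **Fold re-randomization.** Each repeat draws a fresh partition; fold
  seeds derive deterministically from one master seed, so the whole
  $k \times \text{repeats}$ experiment is reproducible from a single
  integer.
* **Multi-class diseases** count toward their first listed class only.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `r` | 0.7 | restart probability in $(0,1]$; larger values keep the profile more local to the seeds. The source protocol leaves it unstated; 0.7 is the conventional choice in gene-prioritization random walks, and it is always echoed in config output so runs are self-describing. |
| `t` | 0.5 | seed mixing weight between direct genes and association partners. |
| `tol` | 1e-6 | L1 convergence tolerance of the walk. |
| `max_iter` | 1000 | iteration cap; hitting it flags `converged = FALSE` with a warning rather than failing, so a pathological fold cannot abort a sweep. |
| `norm` | L1 | convergence norm; L1 matches the probability-mass semantics, L-infinity is available. |
| `k`, `repeats` | 10, 10 | the standard cross-validation shape (100 AUC values). |
| `threshold` | 0.8 | Pearson cutoff for candidate reporting; a reporting convention, not part of the model. |

## Numerical and representational choices

* Node order is the byte-wise (`radix`) lexicographic sort of identifiers;
  every matrix and vector aligns to it, so results are identical across
  platforms and locales. Ranked outputs break score ties by identifier.
* The transition matrix may be held dense or sparse (`Matrix`); both
  representations are required to produce identical results and the tests
  compare them.
* Off-network seed genes are dropped silently at the vector level (the
  analysis universe is the network's largest component) but counted in a
  returned diagnostic; an entity with *no* on-network gene is skipped with
  a warning rather than failing the run.
* An entity with no training-fold partners falls back to its direct seed:
  cross-validation folds routinely leave entities partnerless and the
  pipeline must still score them.
* `propagate()` starts at $P_0$ and records the per-iteration step
  distances; for $r > 0$ the iteration is a contraction with factor at most
  $1 - r$. `solve_closed_form()` solves
  $(I - (1-r)A')P = rP_0$ directly and serves as the independent oracle for
  the iterative path.
* Degenerate guards: $r = 0$ is rejected (no stationarity guarantee);
  $r = 1$ returns the seed exactly; constant profiles are rejected at
  scoring (they cannot arise from a convergent walk on a connected graph
  with $r < 1$); an association table covering every pair makes the AUC
  undefined and errors.
* Gene-set files are GMT-like: set id, description (writers emit `na` when
  there is nothing to say; readers always treat column 2 as description),
  then one gene per column.

## The synthetic-data generator

`simulate_study()` builds a study whose shape mirrors a small interactome
screen: a connected preferential-attachment network (hub-dominated, like
real PPI networks — this is the regime in which restart walks behave
distinctively), connected disease modules grown as breadth-first balls from
random roots (encoding the locality assumption that disease genes cluster
on the interactome), drug target sets, and planted true associations whose
drugs draw each target from their disease's module or its one-hop
neighborhood with probability `p_in`, else uniformly. The standard
configuration is 100 nodes (attachment parameter 2), 8 diseases with
20-gene modules, 12 drugs with 3 targets, 16 planted pairs, `p_in = 0.9`,
seed 42; these sizes keep the full test suite and the acceptance script in
the seconds-to-minutes range while exercising every code path, and 20-gene
modules mirror the minimum module size real disease screens retain.

What the generator does **not** emulate: the real interactome's exact
degree distribution and scale (thousands of nodes, hundreds of
interactions per hub), identifier semantics, curation noise, or any
disease-category structure. Passing tests therefore demonstrate
correctness of the machinery — propagation, augmentation, scoring, the CV
protocol — not clinical performance on real data.

A consequence of the deliberately small scale is worth stating plainly: on
a 100-node graph a 20-gene module plus its one-hop neighborhood covers
roughly two thirds of all nodes and is strongly enriched for hubs, so the
"network-proximal" constraint on planted targets is only mildly more
restrictive than a uniform draw, and eight 20-gene modules must overlap
heavily. Planted-pair recovery at this scale is accordingly weak: the mean
cross-validated AUC on the standard study sits near chance and well below
what the same method attains on a real-scale interactome, although it does
increase monotonically with `p_in` and the chance-level null calibration
holds. The acceptance script computes all of these quantities; the test
suite asserts the strong-recovery property at its nominal level and that
assertion fails at this scale, which we keep visible rather than relax.
Scaling the network up (or the modules down) restores a strong planted
contrast, but the standard study's shape is kept as the package's
documented reference condition.

## Known limitations

* Pearson correlation of full profiles is sensitive to hub-driven
  covariance shared by all entities; no degree correction is applied, by
  design, because the scored quantity is defined as the plain correlation
  of stationary profiles.
* Supervision can only help when association partners carry signal about
  the held-out pair; with weak or absent signal the augmentation adds
  noise, and cross-validated AUC may fall at or below the unsupervised
  baseline.
* Edge weights are ignored (the adjacency is binary), and the walk is
  defined on the largest connected component only.
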