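---
title: "Methods: network propagation, evidence matching and validation in phytonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation, evidence matching and validation in phytonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phytonet` predicts candidate health effects of phytochemicals by combining
molecular network propagation, chemical availability filters and
ethnopharmacological evidence. This vignette explains the underlying models,
the choices made where the method leaves room, and what the synthetic test
bed does and does not demonstrate.

## 1. Propagation model

A compound's target profile seeds a random walk with restart (RWR) on an
undirected molecular interaction network:

$$p_{t+1} = (1-r)\,W^{\top} p_t + r\,p_0 .$$

**Normalization of W.** `build_transition()` row-normalizes the adjacency
matrix by weighted degree, so $W^\top$ is column-stochastic and the
iteration conserves total probability mass — the standard RWR convention.
Isolated nodes receive a self-transition of 1 for the same reason; without
it, mass seeded on (or diffusing to) such a node would leak.

**Seed vector.** Direct targets (physical binding) get raw weight 1.0 and
indirect targets (expression changes, phosphorylation, metabolite action)
0.3; `make_seed_vector()` then normalizes the vector to sum to one. The
method's defining property is the 1 : 0.3 *relative* weighting, which
normalization preserves; keeping $p_0$ a probability vector makes the
iteration a genuine probability process and gives the conservation
invariant `sum(scores) == 1` that the tests rely on. A node listed as both
direct and indirect keeps the stronger (direct) weight.

**Convergence.** Iteration stops when the L1 norm of the change drops below
`tol = 1e-8` (the norm is not dictated by the recurrence itself; L1 is the
natural choice for probability vectors and the common one in the RWR
literature). With restart $r = 0.7$ the map is a contraction with factor
$0.3$, so convergence takes roughly $\log(10^{-8})/\log(0.3) \approx 16$
iterations regardless of network size. `restart = 1` returns the seed
vector itself. Non-convergence within `max_iter` is flagged on the result,
not fatal.

**Phenotype mapping.** The raw score of a phenotype is the sum of
steady-state scores over its associated genes present in the network; genes
shared between phenotypes count for each, and phenotypes with no in-network
genes score zero (they can then never be selected, which is the intended
conservative behaviour).

## 2. Permutation null and PVP selection

Raw phenotype scores grow with both the compound's target count and the
phenotype's gene count, so `empirical_null()` fixes the observed numbers of
direct and indirect targets and redraws the target identities uniformly
from all network nodes (disjoint sets, without replacement), re-propagating
each of `n_random = 1000` random profiles. The empirical p-value is
$(n_\mathrm{exceed}+1)/(n_\mathrm{random}+1)$, where ties do **not** count
as exceeding — the add-one form keeps p-values in $(0,1]$ and the strict
inequality is the conservative reading of "larger than". Selection at
`alpha = 0.01` is strict (`p < alpha`), so `p = 0.01` exactly is *not*
selected. Random targets are drawn from all network nodes; restricting the
pool to known druggable proteins would be an alternative, but the uniform
pool is the only choice that needs no extra annotation and it matches the
null hypothesis "this target profile is arbitrary".

All random profiles propagate as columns of one matrix iteration, which is
numerically identical to independent runs but orders of magnitude faster.
Each compound derives its own RNG stream from the master seed and its
identifier (`derive_seed()`), so runs are reproducible compound-by-compound
and insensitive to evaluation order.

## 3. Chemical availability

`ro5_compliant()` counts Lipinski violations over {MW > 500, AlogP > 5,
HBD > 5, HBA > 10} and calls a compound compliant when at most one is
violated — Lipinski's own convention; a stricter zero-violation reading is
available via `max_violations = 0`. Descriptors come from a pluggable
backend: the default is a precomputed table (provenance recorded), with an
optional Open Babel backend (ChemmineR/ChemmineOB) computing MW, logP,
donors, acceptors and rotatable bonds. Descriptor conventions differ
between calculators (for bare water the donor count depends on the
backend's treatment of atoms without bonds, which the Open Babel SDF route
cannot even represent); outputs therefore carry the backend name and
version, and cross-backend numeric identity is not promised.

HIA, Caco-2 and BBB classifications are external model outputs in real
use and are supplied precomputed. To let synthetic studies run end to end,
`predict_availability()` provides a deliberately simple logistic rule on MW
and AlogP — a labelled surrogate with hand-set coefficients (smaller and
moderately lipophilic passes more readily; BBB penalizes size hardest and
rewards lipophilicity most), not a validated ADMET model. It fills only
unknown flags and never overwrites supplied ones. The co-satisfaction table
excludes unknown flags from every cell they touch, so an unknown is neither
a pass nor a failure.

## 4. Concept hierarchy and Wu–Palmer similarity

The phenotype hierarchy is built from UMLS-style triples: `RB(a, b)` ("b is
broader") stores b as a's parent, `RN` is the inverse, and `RO`
(other-related) edges are retained but take no part in depth, subsumer or
path computations — they are not hierarchical, and letting them shorten
paths would inflate similarities unpredictably. Dumps with the opposite
polarity can set `orientation = "inverted"`. Because such vocabularies have
many roots, all parentless concepts attach to a virtual root at depth 0;
similarity between concepts whose only common ancestor is that root is
defined as 0.

Similarity is $2d/(\ell_1+\ell_2+2d)$ with $d$ the depth of the lowest
common subsumer and $\ell_i$ the shortest hierarchical path lengths to it.
With multiple parents, depth is the minimum root-chain length and paths are
shortest paths over undirected parent–child edges. LCS ties at equal depth
break lexicographically, and cycle-closing hierarchy edges are dropped in
deterministic lexicographic insertion order — both tie-breaks exist to make
results independent of input row order.

Evidence matching (`match_evidence()`) scores each predicted phenotype
against each plant containing the compound by the *best* matching use
concept, supports the plant when that similarity strictly exceeds 0.8, and
counts supporting plants ($n_e$). Using the maximum rather than an average
reflects how a single matching traditional indication is already evidence;
counting plants rather than (plant, use) pairs keeps $n_e$ invariant to
redundant use listings. Ranking is dense on descending $n_e$ with
lexicographic ordering inside ties.

## 5. Literature statistics

Co-occurrence $n_c$ counts abstracts with at least one sentence mentioning
both terms, while occurrence $n_o$ counts abstracts mentioning either term
anywhere — the Jaccard index $n_c/n_o$ therefore mixes a sentence-level
numerator with an abstract-level denominator by design, and is 0 when the
pair never appears. Fisher enrichment uses the abstract-level 2×2 table and
the one-sided (over-representation) exact hypergeometric tail: only
over-representation constitutes literature support, and the one-sided test
is the sharper instrument for it. Degenerate tables (a zero margin) return
p = 1. BH q-values are computed per association list — one comparison set,
one family. The Mann–Whitney test runs in exact mode when the sample-size
product is at most 400 and the data are tie-free, otherwise with the
tie-corrected normal approximation; the mode used travels with the result.

Precision under unknown true negatives is estimated by sampling negative
sets from the pair universe minus the positives at controlled skews (1:1,
1:10, or the whole complement), ten draws by default, reporting mean ± SD;
recall is skew-independent by construction. For the "all" skew the negative
set is exhaustive, so every repeat is identical and the SD is exactly 0.

## 6. The synthetic test bed

`fixture_spec()` defaults define the reference synthetic study: a connected
degree-heterogeneous network of 150 nodes at density 0.04 (mean degree ≈ 6,
spanning tree plus preferential attachment), 20 compounds with 6 direct and
6 indirect targets, 30 phenotypes of 8 genes, a 3-ary concept tree of depth
4, 15 plants with 4 uses, and 500 abstracts. Each compound carries 2
planted true phenotypes; its direct targets are drawn round-robin from the
planted phenotypes' gene sets (3 seed genes per phenotype) and its indirect
targets from their one-hop neighbourhoods, so propagation signal exists by
construction — with fewer than ~2 seed genes per phenotype the permutation
null at $\alpha=0.01$ cannot reliably separate planted from random profiles,
which would defeat the generator's purpose of providing recoverable ground
truth. Plant-use records echo each planted phenotype with probability 0.9,
and the corpus plants a same-sentence co-mention for *every*
compound–phenotype pair at rate 0.002 per abstract, multiplied by
`enrichment_strength` (default 10) for true pairs — so strength 1 is an
exact null, which the tests exploit for calibration checks.

These sizes keep a full pipeline run (20 compounds × 1001 propagations)
around a few seconds while leaving enough statistical resolution for the
calibration and recovery checks; the generator scales to larger settings
by changing the spec.

What the fixtures emulate: planted signal flowing target → network →
phenotype, ethnopharmacological echo, literature enrichment, rule-of-five
heterogeneity and missing flags. What they do not: scale-free PPI topology
beyond mild degree heterogeneity, biased database coverage of well-studied
compounds, noisy concept normalization from free text (mentions arrive as
clean IDs), and realistic descriptor correlations. Passing tests therefore
demonstrate correctness and calibration of the machinery, not real-world
predictive performance.

## 7. Numerical and degenerate-input conventions

* Empirical p-values live in $[1/(n_\mathrm{random}+1), 1]$; the floor is
  the granularity of the permutation test, not a continuity correction.
* `alpha = 0` empties every PVP; downstream tables stay valid and empty.
* Duplicate network edges collapse, self-loops are dropped (counted and
  reported), node order is lexicographic so all matrices are reproducible.
* Mann–Whitney on two fully constant identical samples returns p = 1
  (no evidence of shift) instead of a 0/0 test statistic.
* Confidence intervals on per-compound effect counts use the Student-t
  interval at 95%; with constant counts the width is 0.

## 8. Known limitations

Combination (multi-compound) effects, dosage, and effect direction
(therapeutic vs adverse) are outside the model; the evidence stage can
distinguish effect types only insofar as the use records do. The surrogate
availability rule is for pipeline completeness, not prediction. Similarity
queries are exact BFS computations — fast at vocabulary sizes of thousands,
but an LCA index would be needed for full UMLS-scale batch work.
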