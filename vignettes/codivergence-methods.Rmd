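---
title: "Measuring virus-host co-divergence from tree topologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring virus-host co-divergence from tree topologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codiverge)
```

## The problem

When a virus family co-diverges with its hosts, the virus phylogeny mirrors
the host phylogeny; when viruses jump between host species, the two trees
disagree. `codiverge` quantifies where a virus family sits between these two
extremes using only tree *topology*: virus and host sequences evolve on
wildly different time-scales, so branch lengths are not comparable between
the two trees and are deliberately ignored throughout.

Three complementary statistics are computed by `codivergence()`:

1. the **nPH85 distance**, a normalized count of conflicting clades
   (0 = identical topologies, 1 = no clades in common);
2. the **relative node depth** of each incongruent host clade (are host
   jumps recent, near the tips, or ancient, near the root?);
3. an **event-cost reconciliation** that explains every virus divergence as
   co-divergence, within-host duplication, or a host jump, with extinctions
   charged along the way.

## The nPH85 distance

For a pair of unrooted trees over the same tip set, the classic
Penny–Hendy (PH85) distance counts the bipartitions (splits) not shared
between the two trees. Here the count is *conflict-based*: a split counts as
unique only if it is incompatible with the other tree — the four-intersection
test, `splits_conflict()`. On binary trees this coincides exactly with the
symmetric-difference reading, because a binary tree's split set is maximal
compatible (the test suite verifies this equivalence against an independent
implementation on thousands of random pairs). On polytomous trees the
conflict reading is what gives the metric its key convention: **the distance
between a polytomous clade and any of its resolutions is zero** — a polytomy
is treated as *unresolved*, not as *different*. A plain symmetric difference
would violate this, which is why mere absence of a split is not enough to
count it.

Raw PH85 grows with tree size, so it is normalized by an estimate of the
maximum attainable distance for the pair: the tips of the virus tree are
shuffled 1000 times and the largest PH85 across replicates is the
denominator. The observed (unshuffled) distance is included alongside the
replicates, which caps nPH85 at exactly 1; the running maximum typically
stops moving after a few dozen replicates (`randomized_max_ph85(trace =
TRUE)` exposes the trace). When no conflict is attainable at all — for
example two star trees, where the denominator is zero — nPH85 is defined as
0, the co-divergent extreme. Two properties worth stating:

* nPH85 does not depend on *where* a mismatched clade sits: a single
  rearranged clade near the tips and one near the root give the same value
  (the conflicting-split counts are equal, and the randomization denominator
  depends only on the pair of shapes).
* With the denominator fixed, nPH85 increases with the number of
  conflicting clades.

### Pipeline conventions

Empirical virus trees carry aLRT support values in [0, 1], read from
internal-node Newick labels. Nodes with support strictly below 0.8 (the
conventional aLRT cutoff, false-positive rate below 0.1) are collapsed into
polytomies before the distance is computed; labels that do not parse as a
number in [0, 1] are treated as absent and never collapsed, so literature
host cladograms without supports pass through unchanged. Collapse is applied
to the virus tree in the default pipeline; the function itself works on any
tree.

Virus data sets usually contain more taxa than hosts. The host tree is
therefore expanded to the virus tip set: a host with *m* viruses becomes an
*m*-way polytomy of virus tips. By the polytomy convention this expansion is
distance-neutral, which the suite checks by resolving the expanded tree at
random and confirming nPH85 = 0.

Because collapsing creates polytomies, a single overall nPH85 is reported
together with an uncertainty summary: all polytomies in both trees are
randomly resolved 100 times and nPH85 recomputed per replicate, giving a
mean and an equal-tail 95% percentile range (2.5%–97.5%; the quantile
flavor is R's default type 7). Random resolution merges a uniformly chosen
pair of child lineages at a time, so every refinement is reachable; exact
uniformity over refinements is not claimed, and is irrelevant for the
zero-distance convention. Within the summary, each replicate reuses the same
randomization stream for the null maximum, so replicate-to-replicate spread
reflects topological resolution only — with no polytomies the mean and both
percentiles collapse onto the overall value, as they should.

The tip shuffles are applied to the virus tree (the choice of side is
arbitrary for the pair of shapes involved; both trees' roles are symmetric
in the observed numerator).

## Relative node depth

For rooted trees over the same tip set (host pre-expanded), every nontrivial
host clade — root and leaves excluded — is tested for incompatibility with
the virus tree using the rooted analog of the split-conflict test: two
clades conflict when they overlap without nesting. The *raw depth* of an
incongruent clade is the number of internal nodes in its subtree, counting
its own node and excluding tips, and the *relative depth* divides by the
largest raw depth over all nontrivial internal host nodes. A disrupted
cherry therefore scores 1/(max depth), approaching 0 in large trees, and a
conflict at the deepest nontrivial clade scores exactly 1. Counting internal
nodes rather than all nodes is a convention: it pins the extremes (1 at the
deepest node, minimum 1 raw for a cherry) and only rescales intermediate
values relative to the tips-included count.

## Event-cost reconciliation

Topological distance summarizes *how much* incongruence there is; the
reconciliation explains *why*. `reconcile()` implements the untimed
duplication–transfer–loss model by dynamic programming over (virus node ×
host node): each internal virus node is explained as

* **co-divergence** (cospeciation; default cost 0),
* **duplication** within a host lineage (cost 1), or
* **host jump**: one child lineage transfers to a host lineage neither
  ancestral nor descendant to the current one (cost 1),

with **extinction** (loss; cost 1) charged for each host edge a virus
lineage passes through without diversifying. The default 0/1/1/1 vector is
conservative toward co-divergence. The DP yields the global cost optimum in
polynomial time; `enumerate_optima()` backtracks every co-optimal solution
and reports the distinct event-count vectors with per-event min/max ranges,
so ties are surfaced rather than broken silently. The suite validates the
DP against an exhaustive enumeration of event-labeled placements on small
random instances.

Two deliberate simplifications relative to timed reconciliation tools: the
model is untimed, so transfers are only required to land on a non-ancestral,
non-descendant edge (on some instances every untimed optimum can be
time-inconsistent); and polytomies must be resolved (seeded) before
reconciliation, mirroring the distance pipeline. `reconcile()` reports one
optimum with ties resolved toward co-divergence, then duplication, then host
jump; use `enumerate_optima()` when the range matters. Exhaustive-style
enumeration is intended for trees up to a few dozen tips.

## The simulator

`simulate_tanglegram()` generates the study conditions for validating the
metric:

* the **host tree** grows under a Yule process (uniform random lineage
  splitting). Only the topology matters downstream, so the branching-time
  model is irrelevant and no branch lengths are attached;
* the **virus tree** starts as a tip-relabeled copy of the expanded host
  tree — pure co-divergence — and is then perturbed by `n_switches`
  subtree-prune-regraft (SPR) moves, the topological footprint of a host
  jump and the direct analog of the reconciliation transfer event. Each
  move prunes a uniformly chosen non-root clade and regrafts it on a
  uniformly chosen edge of the remainder; moves that leave the unrooted
  topology unchanged (possible when regrafting next to the old attachment)
  are rejected and redrawn, so every logged switch changes the tree it was
  applied to;
* optional **supports**: a chosen fraction of internal virus nodes receives
  weak support drawn from U[0, 0.8), the rest from U[0.8, 1], to exercise
  the collapse/resolve pipeline;
* optional **multi-virus hosts** via `viruses_per_host`.

Successive switches can partially cancel, so the generator records the
*realized* incongruent-clade count next to the switch log; across a grid of
0–20 switches on 100-tip trees the realized count tracks the applied count
with Spearman correlation above 0.9, and mean nPH85 rises monotonically —
the qualitative validation curve. The suite runs that grid with 20
replicates per point and 100 tip shuffles per distance, sizes chosen so the
whole property runs in about a minute on one core while leaving the
sampling error well below the effects being checked. What the simulator
does **not** emulate: sequence-level noise and estimation error in the
virus tree, non-random taxon sampling, duplication/extinction events, and
literature host cladograms' idiosyncratic polytomies. Passing these
simulations therefore validates the *metric and its pipeline*, not the
difficulty of inferring good trees from data.

## Tanglegrams and family comparisons

`untangle()` reduces line crossings between the two trees by hill-climbing:
internal nodes on alternating sides are visited and their children reordered
by barycenter (mean partner position), keeping a rotation only when it
strictly reduces the crossing count, until no single rotation improves. The
contract is monotone improvement and determinism — this is a heuristic, not
an exact minimizer, and on tiny instances the suite reports its gap to the
exhaustive rotation optimum rather than forcing it to zero. Crossings are
counted as inversions of the induced permutation (verified against a
quadratic pair scan).

`family_comparison()` takes one record per virus family (nPH85, number of
viruses, genome type) and reports Pearson's correlation of nPH85 with the
number of viruses and a Welch two-sample t test of nPH85 between DNA and
RNA families. Welch's variant is used because equal variances between the
genome-type groups should not be assumed; degenerate inputs (zero variance,
a missing group) are flagged and the statistic omitted rather than guessed.

## Numerical conventions and edge cases

* Strict `<` in support collapse: a node with support exactly at the
  threshold is retained.
* nPH85 is 0 whenever the numerator is 0, and whenever the randomized
  maximum is 0.
* All randomness is seeded: resolution, tip shuffles, simulation, and the
  reconciliation's pre-resolution derive independent sub-seeds from the one
  user-supplied seed, so a fit is reproducible end to end and seeded
  operations do not perturb the caller's RNG stream.
* Backtracking compares costs with an absolute tolerance of 1e-9 to be safe
  under non-integer user-supplied event costs.
* Trees are validated on input: unique non-empty tip labels, no unary
  internal nodes (except the degenerate one-tip tree), balanced
  parentheses with the position of the first error reported.

## A worked example

```{r example}
sim <- simulate_tanglegram(n_hosts = 10, n_switches = 3, seed = 5)
fit <- codivergence(sim$host, sim$virus, sim$assoc,
                    n_resolutions = 20, n_randomizations = 200, seed = 1)
summary(fit)
plot(fit)
```

## Limitations

* The nPH85 denominator is a randomized estimate of the maximum distance;
  with very few tips the null space is small and the estimate is exact in
  practice, but it is an approximation by construction.
* The reconciliation is untimed; a timed method can disagree on instances
  where all untimed optima are time-inconsistent.
* Untangling is a local search; the crossing count it returns is an upper
  bound on the true minimum.
* Rooting matters for the depth statistic and the reconciliation; host
  trees should be rooted from external knowledge, and no automatic rooting
  is attempted.
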