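---
title: "Parsimony, stratigraphic congruence and body size: methods behind paleoclad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony, stratigraphic congruence and body size: methods behind paleoclad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoclad)
```

paleoclad re-implements, as one tested pipeline, the computational chain
typically used to place a new fossil baleen whale in a phylogeny and flesh
out its biology: maximum-parsimony analysis of a discrete morphological
matrix built from homoplasy-screened characters, synapomorphy mapping under
ACCTRAN, stratigraphic congruence and minimum divergence dating, a
stratocladistic test of a proposed ancestor-descendant pair, and allometric
body-size estimation from skull measurements. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical choices
made where the design was genuinely open.

## Character matrices and their ambiguities

A `morph_matrix` holds taxa scored for discrete, single-symbol (0-9)
characters. Each cell is a *state set*: determinate observations are
singletons; polymorphic or uncertain observations (`{01}`) are larger sets;
missing (`?`) and inapplicable (`-`) observations are both represented as
the character's full state set. Treating inapplicable like missing is
standard practice in unordered parsimony; nothing in the scoring machinery
distinguishes them, so the distinction is deliberately not carried. A
consequence worth knowing: a cell scored with *every* observed state of a
character is representationally identical to a missing cell, and the
writers emit it as `?`.

Character alphabets are the sorted observed symbols. Text formats (NEXUS,
TNT `xread`) carry no per-character alphabet, so the read/write round-trip
contract holds over observed-state alphabets — the canonical form a parsed
matrix is always in.

Taxon labels are matched across matrices, trees and range tables after
trimming and collapsing whitespace/underscore runs to `_`; mismatched
spellings beyond that are an error, never a silent drop.

## Parsimony scoring

Unordered characters are scored with the Fitch algorithm over bitmask state
sets, vectorized across characters; the score is invariant under re-rooting
and taxa that are entirely missing for a character contribute nothing. The
single ordered character type in the package (the stratigraphic character,
below) is scored by dynamic programming over states with linear cost
`|i - j|`. Trees with a basal polytomy are resolved by rooting along the
first tip's edge — harmless for lengths, which are unrooted quantities —
but polytomies below the root are refused rather than approximated.

Ensemble statistics follow the usual definitions: CI = M/S, RI =
(G-S)/(G-M), RC = CI x RI, HI = 1-CI, where per character `m` is the
minimum conceivable steps (observed states minus one), `s` the observed
steps, and `g` the maximum steps on any tree (determinate cells minus the
modal state count; partially ambiguous cells are left out of `g`, a
documented simplification). Whether parsimony-uninformative characters
enter the CI sums differs between programs and visibly changes the ensemble
CI; `tree_statistics(include_uninformative = )` exposes both conventions,
defaults to including them (the TNT convention), and records the choice in
its output. Characters with `g = m` are always excluded from the RI sums,
where they are undefined.

## Tree search

`branch_and_bound()` enumerates unrooted topologies by stepwise addition
with pruning and returns *all* minimum-length trees; it is exact,
deterministic, and guarded to 12 taxa, where it serves as the oracle
against which the heuristic is tested. `heuristic_search()` is the
classical random-addition-sequence + branch-swapping strategy: each
replicate builds a greedy addition tree from a shuffled taxon order, then
swaps (TBR by default; SPR and NNI available) until no neighbor is
shorter, walking plateaus of equal-length trees (up to 20 per replicate)
so that ties and nearby optima are collected rather than ignored.
Proprietary "new technology" strategies (sectorial searches, ratchet,
tree fusing) are intentionally not reproduced: on matrices of a few dozen
taxa, plain RAS+TBR with the default 100 replicates reliably finds the
optimum and is fully specifiable. The seed is a mandatory part of
`search_config()` (default 1) and is echoed in the result; equal trees are
deduplicated by canonical unrooted topology. Search results report whether
multiple optima exist and their strict consensus; per-tree statistics are
computed on each binary optimum (a consensus with polytomies is reported
topologically, not scored).

## ACCTRAN and synapomorphy mapping

Ancestral states are assigned root-to-tips by dynamic programming. At the
root the lexicographically smallest optimal state is taken; at each other
node, among states minimizing the remaining cost, a state *differing* from
the parent is preferred — taking the change on the current branch rather
than deferring it tipward, which is the accelerated-transformation
convention — with remaining ties again broken lexicographically. Both
tie-break rules are deterministic and documented so mapped changes are
reproducible. Recorded changes per character always sum to that
character's step count.

A change is classified *unambiguous* when every most-parsimonious
reconstruction places a change on that branch with the same derived state,
decided exactly by inside/outside cost tables rather than by sampling
reconstructions. One subtlety: a rooted binary tree's root is a point on
the branch joining its two children, so for a child of the root the
"branch" tested runs through the root to its sibling; without this the
classifier would call changes near the root ambiguous that are in fact
forced on the unrooted tree.

## Homoplasy screening

`screen_characters()` operationalizes the character-selection protocol in
which candidate characters are kept only if they show no homoplasy on
published reference topologies. Published practice often words this as
assessment "by eye"; the only reproducible reading is the per-character
consistency index on the stated reference tree, so that is what is
computed, over the taxa each tree shares with the matrix. A character is
excluded when its CI falls below the threshold (default 1, i.e. any
homoplasy) on *any* reference tree; how verdicts should combine across
several hypotheses is genuinely underdetermined, so the any-tree rule is
the default and an all-tree rule is available. Characters that no
reference tree can score (constant over shared taxa) are retained with a
warning: absence of evidence of homoplasy is not evidence of homoplasy.

## Stratigraphic congruence and dating

The stratigraphic consistency index evaluates every internal non-root
node: the node is consistent when its clade's oldest first appearance
(FAD) is not older than its sister clade's; ties count as consistent,
because stage-resolution ages make strict inequality too brittle. For a
fully dichotomous rooted tree of n tips the denominator is n - 2 (internal
nodes excluding the root), which reproduces the "OTUs minus 2" convention
of the congruence literature; the per-node verdict list is returned
alongside so the arithmetic is auditable. Tips without ranges are pruned
with a warning before evaluation. Ages are treated as points (the FAD,
i.e. the older bound of the stated interval).

Minimum divergence dates are the standard fossil-constrained lower bounds:
a node's age is its clade's oldest FAD, and each branch's ghost-lineage
duration is the parent age minus the child's clade FAD. These are
one-sided estimates by construction — with ranges sampled inside true
lineage durations they can only underestimate — and the synthetic-data
tests verify exactly that bias direction.

## The stratocladistic ancestor-descendant test

`compare_adr()` scores the hypothesis that one terminal is the direct
ancestor of another against the sister-group arrangement, in parsimony
debt. Ancestorization is modeled as the MacClade-style manipulation: the
ancestor tip is deleted and its observed states are fixed as constraints at
the internal node from which the descendant descends (a zero-length
attachment); characters where the ancestor is missing leave the node free.
The debt — constrained length minus the unmodified tree's length — is
provably non-negative and is zero exactly when the ancestor's states match
an unconstrained optimum at that node.

The stratigraphic character folds temporal misfit into tree length: each
taxon's state is the index of the geological-stage bin holding its FAD,
and the character is ordered so crossing k bins costs k steps, with weight
1 per crossing (no separate stratigraphic-debt currency). The default bins
are the late Neogene stages (Tortonian, Messinian, Zanclean, Piacenzian,
Gelasian-to-Recent); these are a reconstruction of common stage-level
practice, clearly labeled as such, and any contiguous old-to-young bin
table can be supplied. Both modes — morphology alone and with the
character — are always reported, since the interesting phenomenon is
precisely how stratigraphic data shift the debt.

## Allometric body size

Four regression equations (all base-10 logarithms; bizygomatic width,
occipital breadth, supraoccipital and condylobasal lengths in mm) estimate
total body length and mass:

1. `log10(L_mm) = 0.92 (log10(BZW) - 1.64) + 2.67`;
2. `M_kg = 4.924e-6 OB^3.858`;
3. `log10(M_kg) = 3.08 log10(L_cm) - 4.84`, inverted to get a length from
   a mass — note the centimetre convention, fixed by reproducing the
   published worked example;
4. `SOL = 0.3937 CBL - 62.803`, inverted for the skull length and
   multiplied by 3 and 4 (skull length being ~25-30% of body length in
   balaenids) to bracket total length. The inverse requires
   `SOL > 62.803` mm.

Equations 1-3 were calibrated outside the family of interest and
overestimate; corrections are applied multiplicatively (`raw * (1 - f)`),
with defaults f = 0.37/0.47 for equation 1 and f = 0.40 for equation 3,
the deviations reported when the regressions were checked against intact
specimens. `consensus_size()` pools corrected lengths into an
order-invariant min-max range. Raw values are always retained next to
corrected ones.

## The synthetic-data generator

The generator exists so that every stage runs against known ground truth
without downloads, and its defaults describe the study conditions the
package targets. Trees are pure-birth with unit rate, root rescaled to
20 Ma — the balaenoid timescale. Characters evolve under the simplest
model matching "unordered and unweighted": equal-rate symmetric (Mk)
transitions, with an expected `rate` changes per character across the tree
(default 1.5, a low-homoplasy regime); homoplasy-free mode instead places
exactly one change per character on a random internal branch, so CI = 1 on
the true tree by construction. Ranges are sampled uniformly inside each
tip's true lineage duration (so estimated node ages are conservative by
construction), and skull measurements are produced by inverting the
allometric equations and applying multiplicative lognormal noise (additive
noise could go negative; default sd 0.05). Every simulator takes its seed
from `sim_config()` and emits its ground truth next to the observables.

What the simulations do *not* emulate: correlated characters and
morphological integration, fossilized-birth-death sampling,
state-dependent rates, and geographic structure. Passing tests therefore
demonstrate correctness of the algorithms under the stated models, not
robustness of the inferences to real-data pathologies.

## Problem sizes, tolerances and degenerate inputs

The test suite works at sizes where independent oracles are exact:
exhaustive enumeration of ancestral-state assignments on trees of up to 6
tips, branch-and-bound comparisons at 8-10 taxa, simulation studies of
10-50 replicates at 8-15 taxa, and the published worked examples, which
are single closed-form evaluations. These sizes were chosen as the
smallest at which each property is non-trivial; all scale upward.

Degenerate inputs are refused loudly rather than patched: empty matrices
and zero-length trees raise undefined-statistics errors, unrooted trees
are rejected where rooting matters (SCI, ACCTRAN), undatable nodes and
FADs outside bin coverage are errors, and branch-and-bound refuses
problems beyond its guard instead of silently degrading. Floating-point
age comparisons use exact `<=` (ties-consistent) on purpose: ages come
from stage tables with identical literals, and an epsilon would hide true
ties.

## Known limitations

* Polytomies below the root are not scored; resolve them or use the
  search functions.
* `g` (maximum steps) ignores partially ambiguous cells, so ensemble RI
  on heavily polymorphic matrices can differ slightly from programs that
  resolve ambiguity during `g` counting.
* The ADR machinery scores specified hypotheses and user-supplied
  topologies; it does not search the space of all ancestorized trees.
* The heuristic search is written for matrices of tens of taxa; hundreds
  of taxa call for dedicated parsimony programs.
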