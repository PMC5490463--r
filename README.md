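# paleoclad

Cladistic analysis of discrete morphological matrices with fossil taxa:
maximum parsimony, stratigraphic congruence, stratocladistic
ancestor–descendant testing, and allometric body-size estimation — the
computational chain behind placing a fossil baleen whale (or any fossil
vertebrate scored for discrete characters) in a dated phylogeny and
estimating its biology.

It is written for paleontologists and systematists who want each step of
that chain reproducible and testable:

* **Parsimony core** — Fitch scoring of unordered characters, exact
  branch-and-bound and random-addition + TBR heuristic searches, ensemble
  indices (CI = M/S, RI = (G−S)/(G−M), RC = CI·RI, HI = 1−CI, with both
  uninformative-character conventions), ACCTRAN ancestral states, and
  exact unambiguous/ambiguous synapomorphy classification.
* **Homoplasy screening** — per-character CI against reference topologies,
  re-enacting "exclude characters with CI < 1" protocols reproducibly.
* **Stratigraphic congruence** — the stratigraphic consistency index
  (SCI = consistent / evaluated internal nodes, the denominator being
  OTUs − 2 on a dichotomous rooted tree), ghost-lineage durations, and
  fossil-constrained minimum divergence dates.
* **Stratocladistics** — the ancestor–descendant test: delete the putative
  ancestor, fix its states at the node subtending the descendant, and
  report the parsimony debt with and without an ordered
  geological-stage-bin stratigraphic character.
* **Body size** — the four-equation allometric protocol (bizygomatic
  width → length; occipital breadth → mass; mass → length; supraoccipital
  → condylobasal length → length bracket) with the published correction
  factors and a consensus range.
* **Synthetic data** — seeded generators for dated trees, Mk characters
  (including a homoplasy-free mode), fossil ranges inside true lineage
  durations, and skull measurements, each emitting its ground truth.

Matrices are read and written in NEXUS and TNT `xread` formats, trees in
Newick, ranges as TSV. A thin CLI covering the whole pipeline ships at
`inst/cli/ppk.R`.

## Worked example: body size of a Pliocene right whale

From the holotype skull measurements (bizygomatic width 1,660 mm,
occipital breadth 353 mm, supraoccipital length 560 mm):

```r
library(paleoclad)
out <- estimate_body_size(bizygomatic_mm = 1660,
                          occipital_breadth_mm = 353,
                          supraoccipital_mm = 560)
for (e in out$estimates) print(e)
print(out$consensus)
#> eq1_bizygomatic: raw 13.30 m | corrected: 8.38, 7.05 m
#> eq2_occipital_mass: raw 33.24 t
#> eq3_mass_to_length: raw 10.95 m | corrected: 6.57 m
#> eq4_supraoccipital: raw 1.58 m
#> consensus body length: 4.7 - 8.4 m; body mass ~ 19.9 t
```

Equation 1 overestimates (~13 m raw) and is reduced by the published
37%/47% deviations to ~8 and ~7 m; the occipital-breadth mass (~33 t)
chained through equation 3 gives ~11 m, corrected by 40% to ~6.6 m (and
~19.9 t); the supraoccipital inversion gives a ~1.6 m skull, bracketing
4.7–6.3 m of body. The consensus range is the spread of the corrected
estimates — a 5–7 m whale by the central methods.

## Worked example: search, congruence, ancestry

```r
cfg <- sim_config(n_taxa = 12, n_char = 80, seed = 42,
                  homoplasy_free = TRUE)
tr  <- simulate_tree(cfg)                      # dated truth, root 20 Ma
m   <- simulate_characters(tr, cfg)$matrix
res <- heuristic_search(m, search_config(replicates = 5, seed = 1))
print(res)
#> parsimony search: best length 80 | 1 tree(s) retained | seed 1

rg <- simulate_ranges(tr, cfg)
print(sci(res$trees[[1]], rg))
#> SCI = 5/10 = 0.500

bins <- data.frame(bin = paste0("b", 1:4), older_ma = c(20, 15, 10, 5),
                   younger_ma = c(15, 10, 5, 0))
cmp <- compare_adr(res$trees[[1]], m, adr_hypothesis("t3", "t5"),
                   ranges = rg, bins = bins)
print(cmp)
#> ADR test: sister length 80 | ADR length 115 | debt 35 -> sister-group
#>   with stratigraphic character: debt 35 -> sister-group
```

Eighty homoplasy-free characters on 12 taxa are solved exactly (length 80,
one change per character, CI = 1 on the recovered tree, which equals the
generating tree). The SCI counts 5 of 10 evaluated internal nodes
consistent with the sampled fossil ranges. The ancestor–descendant test
for two arbitrary tips is, as expected here, heavily rejected: fixing
`t3`'s states at `t5`'s node costs 35 extra steps, and stratigraphy does
not rescue it.

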