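test_that("clade FAD is the oldest first appearance among descendants", {
  tr <- read_tree(text = "((A,B),C);")
  rg <- strat_ranges(c("A", "B", "C"), c(3.6, 5.3, 7.2))
  expect_equal(clade_fad(match("C", tr$tip.label), tr, rg), 7.2)
  cherry <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(clade_fad(cherry, tr, rg), 5.3)
  expect_error(clade_fad(cherry, tr, strat_ranges("C", 7.2)), "undatable")
})

test_that("SCI is 1 on a perfect ladder and matches hand enumeration", {
  tr <- read_tree(text = "((((A,B),C),D),E);")
  rg <- strat_ranges(c("A", "B", "C", "D", "E"), c(1, 2, 3, 4, 5))
  s <- sci(tr, rg)
  expect_equal(s$sci, 1)
  expect_equal(s$evaluated, 3L)  # n - 2 for a binary rooted tree
  # oldest taxon nested deepest: hand-enumerated verdicts
  tr4 <- read_tree(text = "((A,B),(C,D));")
  rg4 <- strat_ranges(c("A", "B", "C", "D"), c(9, 1, 2, 3))
  s4 <- sci(tr4, rg4)
  # node {A,B}: fad 9 vs sister {C,D} fad 3 -> inconsistent
  # node {C,D}: fad 3 vs sister {A,B} fad 9 -> consistent
  expect_equal(s4$consistent, 1L)
  expect_equal(s4$evaluated, 2L)
  expect_equal(s4$sci, 0.5)
  # ties count as consistent
  st <- sci(tr4, strat_ranges(c("A", "B", "C", "D"), c(3, 1, 2, 3)))
  expect_equal(st$sci, 1)
})

test_that("SCI requires a rooted tree, prunes undated tips, and is invariant
           under child permutation", {
  tr <- read_tree(text = "((((A,B),C),D),E);")
  rg <- strat_ranges(c("A", "B", "C", "D", "E"), c(2, 1, 5, 3, 4))
  expect_error(sci(ape::unroot(tr), rg), "rooting-required")
  expect_warning(s <- sci(tr, strat_ranges(c("A", "B", "C", "D"),
                                           c(2, 1, 5, 3))), "pruning")
  expect_equal(s$evaluated, 2L)
  # permuting children leaves the SCI unchanged
  base <- sci(tr, rg)$sci
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(sci(rot, rg)$sci, base)
})

test_that("minimum node ages, ghost lineages and totals are self-consistent", {
  tr <- read_tree(text = "((A,B),C);")
  rg <- strat_ranges(c("A", "B", "C"), c(3.6, 5.3, 6))
  dd <- min_divergence_dates(tr, rg)
  cherry <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(dd$node_ages$min_age_ma[dd$node_ages$node == cherry], 5.3)
  gA <- dd$ghosts$ghost_myr[dd$ghosts$child == match("A", tr$tip.label)]
  expect_equal(gA, 5.3 - 3.6)
  expect_true(all(dd$ghosts$ghost_myr >= 0))
  # brute-force recomputation of the total ghost duration
  ages <- c(stats::setNames(rg$fad_ma, rg$taxon))
  age_of <- function(v) {
    tips <- paleoclad:::.tips_below(tr, v)
    max(ages[tips])
  }
  tot <- sum(vapply(seq_len(nrow(tr$edge)), function(k)
    age_of(tr$edge[k, 1]) - age_of(tr$edge[k, 2]), numeric(1)))
  expect_equal(dd$total_ghost_myr, tot)
  # parent ages never younger than child ages
  expect_true(all(dd$ghosts$ghost_myr >= 0))
})

test_that("named-clade minimum ages are reported", {
  tr <- read_tree(text = "(((A,B),C),D);")
  rg <- strat_ranges(c("A", "B", "C", "D"), c(2, 7, 3, 1))
  dd <- min_divergence_dates(tr, rg, clades = list(core = c("A", "B")))
  expect_equal(unname(dd$clade_ages["core"]), 7)
})

test_that("node ages estimated from sampled ranges never exceed true ages,
           and equal them when sampling hits the origination", {
  for (rep in 1:8) {
    cfg <- sim_config(n_taxa = 12, seed = 400 + rep)
    tr <- simulate_tree(cfg)
    rg <- simulate_ranges(tr, cfg)
    dd <- min_divergence_dates(tr, rg)
    true_ages <- tr$node_ages_ma[dd$node_ages$node]
    expect_true(all(dd$node_ages$min_age_ma <= true_ages + 1e-9),
                label = paste("replicate", rep))
  }
  cfg1 <- sim_config(n_taxa = 10, seed = 12, sampling_fraction = 1)
  tr <- simulate_tree(cfg1)
  rg <- simulate_ranges(tr, cfg1)
  dd <- min_divergence_dates(tr, rg)
  # cherries: both children are tips whose FAD equals the parent age
  kids <- paleoclad:::.children(tr)
  par <- paleoclad:::.parents(tr)
  cherries <- which(vapply(seq_along(kids), function(v)
    length(kids[[v]]) == 2 && all(kids[[v]] <= ape::Ntip(tr)), logical(1)))
  for (v in cherries)
    expect_equal(dd$node_ages$min_age_ma[dd$node_ages$node == v],
                 tr$node_ages_ma[v])
})

test_that("the generating tree is at least as stratigraphically consistent as
           a random tree, on average", {
  set.seed(606)
  diffs <- replicate(50, {
    cfg <- sim_config(n_taxa = 10, seed = sample.int(1e6, 1))
    tr <- simulate_tree(cfg)
    rg <- simulate_ranges(tr, cfg)
    rand <- random_topology(tr$tip.label)
    sci(tr, rg)$sci - sci(rand, rg)$sci
  })
  expect_gt(mean(diffs), 0)
})
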