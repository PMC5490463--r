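test_that("simulated trees are dated, binary, seed-reproducible, and the
           right size", {
  cfg <- sim_config(n_taxa = 42, seed = 8)
  tr <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tr), 42L)
  expect_equal(tr$Nnode, 41L)           # rooted binary: n - 1 internal nodes
  expect_true(ape::is.binary(tr) && ape::is.rooted(tr))
  expect_equal(max(tr$node_ages_ma), cfg$root_age_ma)
  # child ages never exceed parent ages
  par <- paleoclad:::.parents(tr)
  nonroot <- which(par != 0)
  expect_true(all(tr$node_ages_ma[nonroot] <= tr$node_ages_ma[par[nonroot]] + 1e-9))
  tr2 <- simulate_tree(cfg)
  expect_equal(write_tree(tr), write_tree(tr2))
  expect_error(sim_config(n_taxa = 2), "n_taxa")
})

test_that("homoplasy-free characters have CI 1 on the true tree and zero rate
           gives constant characters", {
  cfg <- sim_config(n_taxa = 15, n_char = 50, seed = 2, homoplasy_free = TRUE)
  tr <- simulate_tree(cfg)
  sim <- simulate_characters(tr, cfg)
  ci <- per_character_ci(tr, sim$matrix)
  expect_true(all(ci$ci == 1))
  expect_equal(tree_statistics(tr, sim$matrix)$ci, 1)
  # every character is perfectly screened (all retained)
  scr <- screen_characters(sim$matrix, tr)
  expect_true(all(scr$verdict == "retain"))
  # ground truth changes: one per character
  expect_equal(nrow(sim$ground_truth), n_char(sim$matrix))
  cfg0 <- sim_config(n_taxa = 10, n_char = 20, seed = 3, rate = 0)
  sim0 <- simulate_characters(simulate_tree(cfg0), cfg0)
  expect_true(all(char_min_steps(sim0$matrix) == 0))
  expect_error(sim_config(n_states = 1), "states")
})

test_that("character simulation is seed-deterministic and true changes match
           the emitted matrix", {
  cfg <- sim_config(n_taxa = 10, n_char = 30, seed = 44, rate = 3)
  tr <- simulate_tree(cfg)
  a <- simulate_characters(tr, cfg)
  b <- simulate_characters(tr, cfg)
  expect_true(matrix_identical(a$matrix, b$matrix))
  # parsimony length never exceeds the number of true changes
  expect_lte(fitch_score(tr, a$matrix)$length, nrow(a$ground_truth))
})

test_that("moderate-rate simulations are usually solved exactly by search", {
  set.seed(55)
  hits <- replicate(10, {
    cfg <- sim_config(n_taxa = 8, n_char = 40, rate = 2,
                      seed = sample.int(1e6, 1))
    tr <- simulate_tree(cfg)
    m <- simulate_characters(tr, cfg)$matrix
    hs <- heuristic_search(m, search_config(replicates = 2, seed = 1))
    bb <- branch_and_bound(m)
    hs$length == bb$length
  })
  expect_true(all(hits))
})

test_that("simulated ranges stay inside true lineage durations", {
  for (rep in 1:10) {
    cfg <- sim_config(n_taxa = 12, seed = 700 + rep)
    tr <- simulate_tree(cfg)
    rg <- simulate_ranges(tr, cfg)
    par <- paleoclad:::.parents(tr)
    origin <- tr$node_ages_ma[par[seq_len(ape::Ntip(tr))]]
    idx <- match(tr$tip.label, rg$taxon)
    expect_true(all(rg$fad_ma[idx] <= origin + 1e-9))
    expect_true(all(rg$lad_ma <= rg$fad_ma))
    expect_true(all(rg$lad_ma >= 0))
  }
  expect_error(simulate_ranges(ape::rtree(5), sim_config(n_taxa = 5)),
               "ages")
})

test_that("measurement simulation inverts the allometric equations exactly at
           zero noise and reproducibly otherwise", {
  cfg0 <- sim_config(seed = 5, noise_sd = 0)
  sim <- simulate_measurements(7, cfg0)
  expect_equal(length_from_bizygomatic(sim$measurements$bizygomatic_mm)$raw, 7)
  expect_equal(mass_from_occipital_breadth(
    sim$measurements$occipital_breadth_mm)$mass_kg,
    sim$ground_truth$true_mass_kg, tolerance = 1e-9)
  expect_equal(length_from_mass(sim$ground_truth$true_mass_kg)$raw, 7)
  expect_equal(condylobasal_from_supraoccipital(
    sim$measurements$supraoccipital_mm)$raw * 3.5, 7)
  a <- simulate_measurements(7, sim_config(seed = 6, noise_sd = 0.05))
  b <- simulate_measurements(7, sim_config(seed = 6, noise_sd = 0.05))
  expect_equal(a$measurements, b$measurements)
  expect_error(simulate_measurements(-1, cfg0), "domain")
})

test_that("recovered lengths stay within 15% of truth for 5% noise in nearly
           all draws", {
  recovered <- vapply(1:400, function(i) {
    sim <- simulate_measurements(7, sim_config(seed = i, noise_sd = 0.05))
    length_from_bizygomatic(sim$measurements$bizygomatic_mm)$raw
  }, numeric(1))
  expect_gte(mean(abs(recovered - 7) / 7 < 0.15), 0.95)
})
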