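test_that("fitch_score reproduces hand-derived step counts", {
  m <- morph_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  expect_equal(fitch_score(read_tree(text = "((A,B),(C,D));"), m)$length, 1)
  expect_equal(fitch_score(read_tree(text = "((A,C),(B,D));"), m)$length, 2)
  # constant character contributes nothing
  mc <- morph_matrix(rbind(A = "1", B = "1", C = "1", D = "1"))
  expect_equal(fitch_score(read_tree(text = "((A,B),(C,D));"), mc)$length, 0)
  # all-missing taxa contribute nothing
  mq <- morph_matrix(rbind(A = "0", B = "?", C = "?", D = "1"))
  expect_equal(fitch_score(read_tree(text = "((A,B),(C,D));"), mq)$length, 1)
})

test_that("fitch_score equals exhaustive enumeration on random small cases", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    taxa <- paste0("t", seq_len(n))
    k <- sample(2:3, 1)
    m <- random_matrix(taxa, n_char = 4, k = k, p_missing = 0.15)
    tr <- random_topology(taxa)
    got <- per_character_steps(tr, m)
    want <- vapply(seq_len(n_char(m)), function(j) enum_min_steps(tr, m, j),
                   numeric(1))
    expect_equal(got, want, label = paste("replicate", rep))
  }
})

test_that("characters with k observed states need at least k-1 steps", {
  set.seed(7)
  taxa <- paste0("t", 1:6)
  m <- random_matrix(taxa, n_char = 10, k = 4)
  mins <- char_min_steps(m)
  for (rep in 1:5) {
    s <- per_character_steps(random_topology(taxa), m)
    expect_true(all(s >= mins))
  }
})

test_that("tree length is invariant under re-rooting", {
  set.seed(13)
  taxa <- paste0("t", 1:8)
  m <- random_matrix(taxa, n_char = 12, k = 3, p_missing = 0.1)
  tr <- random_topology(taxa)
  base <- fitch_score(tr, m)$length
  for (og in taxa[2:5]) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(fitch_score(rr, m)$length, base)
  }
})

test_that("fitch lengths agree with phangorn on ambiguity-free matrices", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  taxa <- paste0("t", 1:9)
  cells <- matrix(as.character(sample(0:2, 9 * 15, replace = TRUE)),
                  nrow = 9, dimnames = list(taxa, NULL))
  m <- morph_matrix(cells)
  pd <- phangorn::phyDat(cells, type = "USER", levels = c("0", "1", "2"))
  for (rep in 1:5) {
    tr <- random_topology(taxa)
    expect_equal(fitch_score(tr, m)$length,
                 as.numeric(phangorn::fitch(tr, pd)))
  }
})

test_that("ensemble indices match hand computation and invariants hold", {
  # single binary character 0,0,1,1 on ((A,C),(B,D)): M=1, S=2, G=2
  m <- morph_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  st <- tree_statistics(read_tree(text = "((A,C),(B,D));"), m)
  expect_equal(st$ci, 0.5)
  expect_equal(st$ri, 0)
  expect_equal(st$hi, 1 - st$ci)
  expect_equal(st$rc, st$ci * st$ri)
  expect_equal(st$length, sum(st$per_character_steps))
  # homoplasy-free matrix: CI = 1, HI = 0
  cfg <- sim_config(n_taxa = 10, n_char = 30, seed = 3, homoplasy_free = TRUE)
  tr <- simulate_tree(cfg)
  m2 <- simulate_characters(tr, cfg)$matrix
  st2 <- tree_statistics(tr, m2)
  expect_equal(st2$ci, 1)
  expect_equal(st2$hi, 0)
  expect_error(tree_statistics(tr, m2[, integer(0)]), "undefined-statistics")
})

test_that("CI/RI agree with phangorn on determinate random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  taxa <- paste0("t", 1:8)
  cells <- matrix(as.character(sample(0:1, 8 * 20, replace = TRUE)),
                  nrow = 8, dimnames = list(taxa, NULL))
  m <- morph_matrix(cells)
  pd <- phangorn::phyDat(cells, type = "USER", levels = c("0", "1"))
  tr <- random_topology(taxa)
  st <- tree_statistics(tr, m, include_uninformative = TRUE)
  expect_equal(st$ci, as.numeric(phangorn::CI(tr, pd)))
  expect_equal(st$ri, as.numeric(phangorn::RI(tr, pd)))
})

test_that("branch-and-bound finds the true tree and refuses big inputs", {
  # 4-taxon perfectly compatible matrix -> single true topology
  m <- morph_matrix(rbind(A = c("0", "0"), B = c("0", "0"),
                          C = c("1", "0"), D = c("1", "1")))
  # char 1 marks {C,D}, char 2 is an autapomorphy of D: compatible, one optimum
  bb <- branch_and_bound(m)
  expect_equal(bb$length, 2)
  expect_equal(length(bb$trees), 1L)
  expect_true(same_topology(bb$trees[[1]], read_tree(text = "((A,B),(C,D));")))
  # 3 taxa: single unrooted topology regardless of data
  m3 <- morph_matrix(rbind(A = "0", B = "1", C = "0"))
  expect_equal(length(branch_and_bound(m3)$trees), 1L)
  big <- random_matrix(paste0("t", 1:13), 5)
  expect_error(branch_and_bound(big), "refusal")
})

test_that("heuristic search matches branch-and-bound optimum", {
  set.seed(17)
  for (rep in 1:3) {
    cfg <- sim_config(n_taxa = 8, n_char = 15, seed = 100 + rep, rate = 6,
                      n_states = 2)
    tr <- simulate_tree(cfg)
    m <- simulate_characters(tr, cfg)$matrix
    bb <- branch_and_bound(m)
    hs <- heuristic_search(m, search_config(replicates = 3, seed = rep))
    expect_equal(hs$length, bb$length, label = paste("replicate", rep))
    expect_true(hs$length <= fitch_score(tr, m)$length)
  }
})

test_that("heuristic search is deterministic for a fixed seed and recovers
           the generating tree from homoplasy-free data", {
  cfg <- sim_config(n_taxa = 12, n_char = 60, seed = 9, homoplasy_free = TRUE)
  tr <- simulate_tree(cfg)
  m <- simulate_characters(tr, cfg)$matrix
  h1 <- heuristic_search(m, search_config(replicates = 2, seed = 4))
  h2 <- heuristic_search(m, search_config(replicates = 2, seed = 4))
  expect_equal(write_tree(h1$trees), write_tree(h2$trees))
  expect_equal(h1$length, sum(char_min_steps(m)))
  expect_true(any(vapply(h1$trees, same_topology, logical(1), b = tr)))
})
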