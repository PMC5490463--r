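test_that("the stratigraphic character bins FADs and is costed linearly", {
  # two taxa in adjacent bins: 1 step on any tree
  rg <- strat_ranges(c("A", "B", "C"), c(6, 4, 4.5))
  sc <- build_strat_character(rg)    # Messinian (1) vs Zanclean (2)
  expect_equal(unlist(matrix_cells(sc)[, 1]), c(A = "1", B = "2", C = "2"))
  expect_equal(per_character_steps(read_tree(text = "((A,B),C);"), sc), 1)
  # all taxa in one bin: constant, 0 steps
  rg1 <- strat_ranges(c("A", "B", "C"), c(3, 3.1, 2.9))
  sc1 <- build_strat_character(rg1)
  expect_equal(per_character_steps(read_tree(text = "((A,B),C);"), sc1), 0)
  # FAD outside coverage errors
  expect_error(build_strat_character(strat_ranges("A", 30)), "binning")
})

test_that("ordered 5-bin ladder costs 4 steps in either orientation,
           matching exhaustive enumeration", {
  bins <- data.frame(bin = letters[1:5], older_ma = 5:1, younger_ma = 4:0)
  rg <- strat_ranges(paste0("t", 1:5), c(4.5, 3.5, 2.5, 1.5, 0.5))
  sc <- build_strat_character(rg, bins)
  ladder <- read_tree(text = "((((t1,t2),t3),t4),t5);")
  reversed <- read_tree(text = "((((t5,t4),t3),t2),t1);")
  expect_equal(per_character_steps(ladder, sc), 4)
  expect_equal(per_character_steps(reversed, sc), 4)
  expect_equal(enum_min_steps(ladder, sc, 1), 4)
  expect_equal(enum_min_steps(reversed, sc, 1), 4)
})

test_that("ADR debt matches exhaustive constrained enumeration on small
           hand-built cases", {
  # ancestor X with one derived autapomorphy: debt exactly +1
  m <- morph_matrix(rbind(A = c("0", "0"), B = c("0", "0"),
                          D = c("1", "0"), X = c("1", "1")))
  tr <- read_tree(text = "((A,B),(D,X));")
  cmp <- compare_adr(tr, m, adr_hypothesis("X", "D"))
  expect_equal(cmp$debt_morphology, 1)
  expect_equal(cmp$verdict_morphology, "sister-group")
  # ancestor matching the unconstrained optimum: zero debt
  m0 <- morph_matrix(rbind(A = c("0", "0"), B = c("0", "0"),
                           D = c("1", "0"), X = c("1", "0")))
  cmp0 <- compare_adr(tr, m0, adr_hypothesis("X", "D"))
  expect_equal(cmp0$debt_morphology, 0)
  expect_false(cmp0$verdict_morphology == "sister-group")
})

test_that("adr_score agrees with brute-force constrained enumeration on
           random instances", {
  set.seed(909)
  for (rep in 1:6) {
    n <- sample(5:6, 1)
    taxa <- c(paste0("t", seq_len(n - 1)), "anc")
    m <- random_matrix(taxa, n_char = 5, k = 2, p_missing = 0.1)
    tr <- random_topology(taxa)
    des <- setdiff(taxa, "anc")[1]
    sc <- adr_score(tr, m, adr_hypothesis("anc", des))
    # oracle: prune ancestor, enumerate with the constrained node
    pruned <- ape::drop.tip(tr, "anc")
    ptree <- paleoclad:::.prepare_tree(pruned, m)
    node <- sc$constrained_node
    anc_row <- match("anc", m$taxa)
    miss <- paleoclad:::.missing_cells(m)[anc_row, ]
    want <- sum(vapply(seq_len(n_char(m)), function(j) {
      if (miss[j]) return(enum_min_steps(ptree, m, j))
      k <- length(m$alphabets[[j]])
      states <- which(bitwAnd(bitwShiftR(m$masks[anc_row, j],
                                         seq_len(k) - 1L), 1L) == 1L)
      enum_constrained(ptree, m, j, node, states)
    }, numeric(1)))
    expect_equal(sc$length, want, label = paste("replicate", rep))
    # debt is never negative
    expect_gte(sc$length, 0)
  }
})

test_that("an all-missing ancestor leaves the pruned-tree length unchanged", {
  taxa <- paste0("t", 1:6)
  set.seed(14)
  m <- random_matrix(taxa, n_char = 8, k = 2)
  cells <- matrix_cells(m)
  for (j in seq_len(n_char(m))) cells[[6, j]] <- "?"
  m2 <- morph_matrix(cells, taxa = taxa, alphabets = m$alphabets)
  tr <- random_topology(taxa)
  sc <- adr_score(tr, m2, adr_hypothesis("t6", "t1"))
  pruned <- ape::drop.tip(tr, "t6")
  expect_equal(sc$length, fitch_score(pruned, m2)$length)
})

test_that("adding the stratigraphic character shifts the debt when the
           ancestor is older than its descendant", {
  # ancestor older (Piacenzian) than descendant (Gelasian+): ancestry is
  # stratigraphically free, sisterhood pays the ordered character more
  m <- morph_matrix(rbind(A = c("0"), B = c("0"), D = c("1"), X = c("1")))
  tr <- read_tree(text = "((A,B),(D,X));")
  rg <- strat_ranges(c("A", "B", "D", "X"), c(9, 8, 1, 3))
  cmp <- compare_adr(tr, m, adr_hypothesis("X", "D"), ranges = rg)
  expect_true(!is.null(cmp$debt_with_strat))
  expect_lte(cmp$debt_with_strat, cmp$debt_morphology)
})

test_that("simulated true ancestors are mostly preferred or tied by the test", {
  set.seed(321)
  verdicts <- replicate(50, {
    # a 5-taxon tree where 'anc' truly sits at the node subtending 'des':
    # give the ancestor exactly the states optimal at that node
    taxa <- c("o1", "o2", "s1", "des")
    m <- random_matrix(taxa, n_char = 6, k = 2)
    tr <- read_tree(text = "((o1,o2),(s1,des));")
    map <- acctran_optimize(tr, m)
    node <- paleoclad:::.parents(map$tree)[match("des", map$tree$tip.label)]
    anc_states <- map$states[node, ]
    cells <- rbind(matrix_cells(m),
                   matrix(as.list(anc_states), nrow = 1))
    rownames(cells) <- c(taxa, "anc")
    m2 <- morph_matrix(cells, taxa = rownames(cells))
    tr2 <- read_tree(text = "((o1,o2),(s1,(des,anc)));")
    cmp <- compare_adr(tr2, m2, adr_hypothesis("anc", "des"))
    cmp$verdict_morphology
  })
  expect_gt(mean(verdicts != "sister-group"), 0.5)
})
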