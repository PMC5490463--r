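# Independent brute-force oracles: enumerate every assignment of states to
# internal nodes and take the cheapest.  Exponential, used only on tiny
# trees; deliberately shares no code with the package's DP/Fitch engines.

# minimal steps of character j on `tree` by exhaustive enumeration;
# cost = 0/1 (unordered) or |i-j| over alphabet ranks (ordered);
# `constrain` optionally restricts one internal node's allowed states
enum_min_steps <- function(tree, m, j, constrain = NULL) {
  # keep node ids stable when a constraint refers to them
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    tree <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1],
                      resolve.root = TRUE)
  tree <- reorder(tree, "postorder")
  ntip <- ape::Ntip(tree)
  alpha <- m$alphabets[[j]]
  k <- length(alpha)
  cells <- matrix_cells(m)
  tip_states <- lapply(tree$tip.label, function(tl)
    match(cells[[match(tl, m$taxa), j]], alpha))
  internal <- sort(unique(tree$edge[, 1]))
  cost <- if (m$ordered[j]) function(a, b) abs(a - b)
          else function(a, b) as.numeric(a != b)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- grid[g, ]
    if (!is.null(constrain)) {
      s <- assign[match(constrain$node, internal)]
      if (!(s %in% constrain$states)) next
    }
    state_of <- function(v) assign[match(v, internal)]
    total <- 0
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- state_of(tree$edge[e, 1])
      chn <- tree$edge[e, 2]
      if (chn <= ntip) {
        opts <- tip_states[[chn]]
        total <- total + min(vapply(opts, function(s) cost(p, s), numeric(1)))
      } else total <- total + cost(p, state_of(chn))
      if (total >= best) { ok <- FALSE; break }
    }
    if (ok) best <- min(best, total)
  }
  best
}

enum_constrained <- function(tree, m, j, node, states) {
  enum_min_steps(tree, m, j, constrain = list(node = node, states = states))
}

enum_tree_length <- function(tree, m) {
  sum(vapply(seq_len(n_char(m)), function(j) enum_min_steps(tree, m, j),
             numeric(1)) * m$weights)
}

# random small matrix over taxa labels, states 0..(k-1), optional missing
random_matrix <- function(taxa, n_char, k = 2, p_missing = 0) {
  cells <- matrix(as.character(sample(0:(k - 1), length(taxa) * n_char,
                                      replace = TRUE)),
                  nrow = length(taxa), dimnames = list(taxa, NULL))
  if (p_missing > 0) {
    hit <- runif(length(cells)) < p_missing
    cells[hit] <- "?"
  }
  morph_matrix(cells)
}

random_topology <- function(taxa) {
  tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
  tr$edge.length <- NULL
  tr
}
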