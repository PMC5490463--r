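#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator.  Defaults mirror
#' the study system the package targets: a balaenoid-like clade of a few
#' dozen taxa evolving low-homoplasy unordered characters on a
#' pure-birth tree whose root is scaled to 20 Ma, with fossil ranges
#' sampled inside true lineage durations.
#'
#' @param n_taxa number of tips (>= 3).
#' @param n_char number of characters.
#' @param n_states states per character (>= 2).
#' @param rate expected number of changes per character across the tree
#'   (ignored in homoplasy-free mode).
#' @param homoplasy_free place exactly one change per character on a
#'   random internal branch, guaranteeing per-character CI = 1 on the
#'   true tree.
#' @param root_age_ma age of the root (Ma); branch lengths are scaled to
#'   it.
#' @param sampling_fraction position of the sampled FAD within each
#'   tip's true lineage duration: 1 = at the true origination (oldest
#'   possible), 0 = at the tip's end; `NA` (default) samples uniformly.
#' @param noise_sd standard deviation of the multiplicative lognormal
#'   measurement noise.
#' @param seed mandatory random seed.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_taxa = 20L, n_char = 100L, n_states = 2L,
                       rate = 1.5, homoplasy_free = FALSE,
                       root_age_ma = 20, sampling_fraction = NA,
                       noise_sd = 0.05, seed = 1L) {
  stopifnot(n_taxa >= 3L, n_char >= 1L, root_age_ma > 0, noise_sd >= 0,
            is.numeric(seed))
  if (n_states < 2L) stop("config error: need at least 2 states")
  if (!homoplasy_free && rate < 0) stop("config error: negative rate")
  structure(list(n_taxa = as.integer(n_taxa), n_char = as.integer(n_char),
                 n_states = as.integer(n_states), rate = rate,
                 homoplasy_free = homoplasy_free,
                 root_age_ma = root_age_ma,
                 sampling_fraction = sampling_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a dated rooted binary tree
#'
#' Pure-birth (Yule) tree with unit birth rate, rescaled so the root sits
#' at `config$root_age_ma`.  Node ages decrease root to tips; extant tips
#' sit at 0.
#'
#' @param config a [sim_config()].
#' @return a `phylo` with `node_ages_ma` (vector over all node ids) and
#'   tips labeled `t1..tn`.
#' @export
simulate_tree <- function(config = sim_config()) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  tree <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths) - depths
  scale <- config$root_age_ma / max(ages)
  ages <- ages * scale
  tree$edge.length <- tree$edge.length * scale
  tree$node_ages_ma <- ages
  tree$tip.label <- paste0("t", seq_len(config$n_taxa))
  tree
}

#' Simulate discrete characters on a tree
#'
#' Mk-type evolution: characters change along branches under an
#' equal-rate symmetric model among `n_states` states, the per-character
#' expected number of changes across the whole tree being `config$rate`.
#' In homoplasy-free mode each character instead receives exactly one
#' 0->1 change on one random internal branch, so every character has
#' CI = 1 on the generating tree.
#'
#' @param tree a dated tree from [simulate_tree()].
#' @param config a [sim_config()].
#' @return list with `matrix` (a [morph_matrix] over the tips) and
#'   `ground_truth` (data frame of true changes: `character`, `node`
#'   = child end of the branch).
#' @export
simulate_characters <- function(tree, config = sim_config()) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed + 1L)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  e <- stats::reorder(tree, "postorder")$edge
  preorder <- rev(seq_len(nrow(e)))
  symbols <- as.character(seq_len(config$n_states) - 1L)
  cells <- matrix("0", ntip, config$n_char)
  truth <- list()
  if (config$homoplasy_free) {
    internal_edges <- which(e[preorder, 2L] > ntip)
    for (j in seq_len(config$n_char)) {
      pick <- preorder[if (length(internal_edges))
        sample(internal_edges, 1L) else sample(length(preorder), 1L)]
      below <- .descendant_tips(tree, e[pick, 2L])
      cells[below, j] <- "1"
      truth[[j]] <- data.frame(character = j, node = e[pick, 2L],
                               from = "0", to = "1")
    }
  } else {
    total_len <- sum(tree$edge.length)
    for (j in seq_len(config$n_char)) {
      state <- integer(nnode)
      state[root] <- sample.int(config$n_states, 1L) - 1L
      rows <- list()
      for (k in preorder) {
        p <- e[k, 1L]; ch <- e[k, 2L]
        s <- state[p]
        n_changes <- stats::rpois(1L, config$rate *
                                    tree$edge.length[match(ch, tree$edge[, 2L])] /
                                    total_len)
        for (z in seq_len(n_changes)) {
          new <- sample(setdiff(seq_len(config$n_states) - 1L, s), 1L)
          rows[[length(rows) + 1L]] <- data.frame(character = j, node = ch,
                                                  from = as.character(s),
                                                  to = as.character(new))
          s <- new
        }
        state[ch] <- s
      }
      cells[seq_len(ntip), j] <- as.character(state[seq_len(ntip)])
      if (length(rows)) truth[[length(truth) + 1L]] <- do.call(rbind, rows)
    }
  }
  rownames(cells) <- tree$tip.label
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(character = integer(0), node = integer(0),
                           from = character(0), to = character(0))
  m <- morph_matrix(cells, taxa = tree$tip.label,
                    alphabets = replicate(config$n_char, symbols,
                                          simplify = FALSE))
  list(matrix = m, ground_truth = truth)
}

#' Simulate fossil ranges inside true lineage durations
#'
#' Each tip's lineage runs from its origination (the age of its parent
#' node) to the tip's own age.  The FAD is placed inside that interval
#' (uniformly, or at the fixed `sampling_fraction`), so sampled FADs
#' never pre-date the true origination and minimum divergence dates
#' estimated from them underestimate the true node ages.  The LAD is
#' uniform between the tip age and the FAD.
#'
#' @param tree a dated tree from [simulate_tree()] (needs
#'   `node_ages_ma`).
#' @param config a [sim_config()].
#' @return a [strat_ranges()] table over the tips.
#' @export
simulate_ranges <- function(tree, config = sim_config()) {
  if (is.null(tree$node_ages_ma))
    stop("config error: tree has no node ages; use simulate_tree()")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed + 2L)
  ntip <- ape::Ntip(tree)
  par <- .parents(tree)
  ages <- tree$node_ages_ma
  fad <- numeric(ntip); lad <- numeric(ntip)
  for (i in seq_len(ntip)) {
    origin <- ages[par[i]]
    end <- ages[i]
    f <- if (is.na(config$sampling_fraction)) stats::runif(1L)
         else config$sampling_fraction
    fad[i] <- end + f * (origin - end)
    lad[i] <- end + stats::runif(1L) * (fad[i] - end)
  }
  strat_ranges(tree$tip.label, fad, lad)
}

#' Simulate skull measurements from a true body length
#'
#' Inverts the allometric equations (see [body_size]) at `true_length_m`
#' and perturbs each measurement with multiplicative lognormal noise of
#' scale `config$noise_sd` (additive noise could produce impossible
#' negative measurements).  With zero noise the measurements round-trip:
#' feeding them back through the body-size equations recovers the true
#' raw length exactly.
#'
#' The condylobasal length is generated as `true_length / 3.5` (skull
#' about 25-30% of body length).
#'
#' @param true_length_m true total body length (m).
#' @param config a [sim_config()].
#' @return list with `measurements` (named list: `bizygomatic_mm`,
#'   `occipital_breadth_mm`, `supraoccipital_mm`) and `ground_truth`
#'   (`true_length_m`, `true_mass_kg`).
#' @export
simulate_measurements <- function(true_length_m, config = sim_config()) {
  if (!is.numeric(true_length_m) || true_length_m <= 0)
    stop("domain error: true length must be positive")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed + 3L)
  len_mm <- true_length_m * 1000
  bzw <- 10^((log10(len_mm) - 2.67) / 0.92 + 1.64)
  mass_kg <- 10^(3.08 * log10(true_length_m * 100) - 4.84)
  ob <- (mass_kg / 4.924e-6)^(1 / 3.858)
  cbl_mm <- len_mm / 3.5
  sol <- 0.3937 * cbl_mm - 62.803
  noise <- function(x) x * exp(stats::rnorm(1L, 0, config$noise_sd))
  list(measurements = list(bizygomatic_mm = noise(bzw),
                           occipital_breadth_mm = noise(ob),
                           supraoccipital_mm = noise(sol)),
       ground_truth = list(true_length_m = true_length_m,
                           true_mass_kg = mass_kg))
}
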