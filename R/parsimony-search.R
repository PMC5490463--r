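#' Search configuration for heuristic parsimony search
#'
#' @param replicates number of random-addition-sequence replicates
#'   (default 100, the convention for matrices of a few dozen taxa).
#' @param rearrangement branch-swapping operator: `"TBR"` (default),
#'   `"SPR"` or `"NNI"`.
#' @param seed mandatory random seed (default 1); recorded in the output
#'   so searches are reproducible.
#' @param max_trees maximum number of equally parsimonious trees
#'   retained.
#' @return a list of class `"search_config"`.
#' @export
search_config <- function(replicates = 100L, rearrangement = c("TBR", "SPR", "NNI"),
                          seed = 1L, max_trees = 100L) {
  rearrangement <- match.arg(rearrangement)
  stopifnot(replicates >= 1L, max_trees >= 1L, is.numeric(seed))
  structure(list(replicates = as.integer(replicates),
                 rearrangement = rearrangement,
                 seed = as.integer(seed),
                 max_trees = as.integer(max_trees)),
            class = "search_config")
}

# ---- internal tree-manipulation helpers (unrooted topologies stored as
# ---- arbitrarily rooted binary phylo objects with unit branch lengths)

.unit_lengths <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

.tip_tree <- function(label) {
  tr <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
             Nnode = 1L, edge.length = 1)
  class(tr) <- "phylo"
  tr
}

# child nodes defining distinct unrooted edges (drops one root-child edge)
.insertion_points <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  setdiff(tree$edge[, 2L], kids[1L])
}

.insert_tip <- function(tree, label, where) {
  out <- ape::bind.tree(.unit_lengths(tree), .tip_tree(label),
                        where = where, position = 0.5)
  .unit_lengths(out)
}

# canonical newick of the unrooted topology (rooted at smallest tip,
# children sorted); used to deduplicate and compare trees
.topo_key <- function(tree) {
  tree <- ape::root(ape::unroot(.unit_lengths(tree)),
                    outgroup = sort(tree$tip.label)[1L], resolve.root = TRUE)
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    parts <- sort(vapply(kids[[as.character(v)]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(ntip + 1L)
}

#' Compare two trees as unrooted topologies
#'
#' @param a,b `phylo` objects over the same tip set.
#' @return `TRUE` when the unrooted bipartition sets are identical.
#' @export
same_topology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  identical(.topo_key(a), .topo_key(b))
}

.tips_below <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[.descendant_tips(tree, node)]
}

.descendant_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  e <- tree$edge
  stack <- node
  tips <- integer(0)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= ntip) tips <- c(tips, v)
    else stack <- c(stack, e[e[, 1L] == v, 2L])
  }
  tips
}

# all reattachment-ready rootings of a pruned clade (TBR); a clade with
# < 3 tips has a single unrooted shape
.clade_rerootings <- function(clade) {
  if (ape::Ntip(clade) < 3L) return(list(clade))
  un <- ape::unroot(.unit_lengths(clade))
  keys <- character(0)
  out <- list()
  for (child in .insertion_points(un)) {
    grp <- .tips_below(un, child)
    if (length(grp) == ape::Ntip(un)) next
    r <- tryCatch(ape::root(un, outgroup = grp, resolve.root = TRUE),
                  error = function(e) NULL)
    if (is.null(r)) next
    k <- ape::write.tree(r)
    if (!(k %in% keys)) { keys <- c(keys, k); out <- c(out, list(r)) }
  }
  if (!length(out)) list(clade) else out
}

# neighborhood of an unrooted topology under NNI / SPR / TBR
.neighbors <- function(tree, operator = "TBR") {
  tree <- .unit_lengths(tree)
  ntip <- ape::Ntip(tree)
  out <- list()
  if (operator == "NNI") {
    nb <- tryCatch(ape::nni(tree), error = function(e) NULL)
    if (!is.null(nb)) out <- unclass(nb)
    return(out)
  }
  for (node in .insertion_points(tree)) {
    clade_tips <- .tips_below(tree, node)
    rest_n <- ntip - length(clade_tips)
    if (rest_n < 3L || length(clade_tips) < 1L) next
    rest <- ape::drop.tip(tree, clade_tips)
    if (is.null(rest)) next
    rest <- .unit_lengths(rest)
    clade <- if (length(clade_tips) == 1L) .tip_tree(clade_tips)
             else .unit_lengths(ape::extract.clade(tree, node))
    clades <- if (operator == "TBR") .clade_rerootings(clade) else list(clade)
    for (cl in clades) {
      for (at in .insertion_points(rest)) {
        cand <- tryCatch(ape::bind.tree(rest, .unit_lengths(cl),
                                        where = at, position = 0.5),
                         error = function(e) NULL)
        if (!is.null(cand)) out <- c(out, list(.unit_lengths(cand)))
      }
    }
  }
  out
}

# greedy random-addition-sequence starting tree
.random_addition_tree <- function(m, order_taxa) {
  t1 <- order_taxa[1L]; t2 <- order_taxa[2L]; t3 <- order_taxa[3L]
  tree <- read_tree(text = sprintf("(%s,(%s,%s));", t1, t2, t3))
  tree <- .unit_lengths(tree)
  for (tx in order_taxa[-(1:3)]) {
    sub <- m[c(tree$tip.label, tx), ]
    best <- NULL; best_len <- Inf
    for (at in .insertion_points(tree)) {
      cand <- .insert_tip(tree, tx, at)
      len <- fitch_score(cand, sub)$length
      if (len < best_len) { best_len <- len; best <- cand }
    }
    tree <- best
  }
  tree
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition-sequence starting trees followed by branch swapping
#' (TBR by default), repeated over `config$replicates` replicates.  All
#' shortest trees found (up to `config$max_trees`, compared as unrooted
#' topologies) are returned with their statistics and strict consensus.
#' Results are reproducible given `config$seed`.
#'
#' @param m a [morph_matrix] with at least 4 taxa.
#' @param config a [search_config()].
#' @param include_uninformative passed to [tree_statistics()].
#' @return a list of class `"parsimony_search"`: `trees` (`multiPhylo`),
#'   `length`, `statistics` (per tree), `consensus` (strict; `NULL` for a
#'   single optimum), `multiple_optima`, `config`.
#' @export
heuristic_search <- function(m, config = search_config(),
                             include_uninformative = TRUE) {
  if (n_taxa(m) < 4L) stop("heuristic search requires at least 4 taxa")
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(config$seed)
  lower_bound <- sum(m$weights * char_min_steps(m))
  best_len <- Inf
  best <- list(); best_keys <- character(0)
  offer <- function(tree, len) {
    if (len > best_len) return(invisible())
    if (len < best_len) { best_len <<- len; best <<- list(); best_keys <<- character(0) }
    if (length(best) >= config$max_trees) return(invisible())
    key <- .topo_key(tree)
    if (!(key %in% best_keys)) {
      best_keys <<- c(best_keys, key)
      best <<- c(best, list(tree))
    }
    invisible()
  }
  plateau_cap <- min(20L, config$max_trees)
  for (rep in seq_len(config$replicates)) {
    ord <- sample(m$taxa)
    tree <- .random_addition_tree(m, ord)
    len <- fitch_score(tree, m)$length
    # swap through the whole plateau of equal-length trees, restarting the
    # plateau whenever a shorter tree is found
    pool <- list(tree)
    keys <- .topo_key(tree)
    i <- 1L
    while (i <= length(pool) && i <= plateau_cap && len > lower_bound) {
      nb <- .neighbors(pool[[i]], config$rearrangement)
      if (!length(nb)) break
      lens <- vapply(nb, function(tr) fitch_score(tr, m)$length, numeric(1))
      if (min(lens) < len) {
        len <- min(lens)
        pool <- nb[lens == len]
        keys <- vapply(pool, .topo_key, character(1))
        dup <- duplicated(keys)
        pool <- pool[!dup]; keys <- keys[!dup]
        i <- 1L
        next
      }
      for (k in which(lens == len)) {
        if (length(pool) >= plateau_cap) break
        key <- .topo_key(nb[[k]])
        if (!(key %in% keys)) {
          keys <- c(keys, key)
          pool <- c(pool, list(nb[[k]]))
        }
      }
      i <- i + 1L
    }
    for (tr in pool) offer(tr, len)
  }
  .search_result(best, best_len, m, config, include_uninformative)
}

.search_result <- function(trees, len, m, config, include_uninformative) {
  stats <- lapply(trees, tree_statistics, m = m,
                  include_uninformative = include_uninformative)
  class(trees) <- "multiPhylo"
  cons <- if (length(trees) > 1L)
    ape::consensus(trees, p = 1, rooted = FALSE) else NULL
  structure(list(trees = trees, length = len, statistics = stats,
                 consensus = cons, multiple_optima = length(trees) > 1L,
                 config = config),
            class = "parsimony_search")
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("parsimony search: best length", x$length, "|",
      length(x$trees), "tree(s) retained",
      if (!is.null(x$config)) paste0("| seed ", x$config$seed), "\n")
  invisible(x)
}

#' Exact branch-and-bound parsimony search
#'
#' Enumerates unrooted binary topologies by stepwise taxon addition,
#' pruning partial trees whose length already exceeds the best complete
#' tree.  Returns every minimum-length topology.  Intended as the exact
#' oracle for [heuristic_search()]; guarded to small problems.
#'
#' @param m a [morph_matrix].
#' @param max_taxa refusal guard (default 12).
#' @return a `"parsimony_search"` list as for [heuristic_search()].
#' @export
branch_and_bound <- function(m, max_taxa = 12L) {
  n <- n_taxa(m)
  if (n > max_taxa)
    stop("refusal error: ", n, " taxa exceeds the branch-and-bound guard (",
         max_taxa, "); use heuristic_search()")
  if (n < 3L) stop("need at least 3 taxa")
  taxa <- m$taxa
  start <- .unit_lengths(read_tree(text = sprintf("(%s,(%s,%s));",
                                                  taxa[1L], taxa[2L], taxa[3L])))
  best_len <- Inf
  best <- list(); best_keys <- character(0)
  recurse <- function(tree, k) {
    len <- fitch_score(tree, m[tree$tip.label, ])$length
    if (len > best_len) return(invisible())
    if (k > n) {
      if (len < best_len) {
        best_len <<- len; best <<- list(); best_keys <<- character(0)
      }
      key <- .topo_key(tree)
      if (!(key %in% best_keys)) {
        best_keys <<- c(best_keys, key)
        best <<- c(best, list(tree))
      }
      return(invisible())
    }
    for (at in .insertion_points(tree))
      recurse(.insert_tip(tree, taxa[k], at), k + 1L)
    invisible()
  }
  recurse(start, 4L)
  .search_result(best, best_len, m, NULL, TRUE)
}
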