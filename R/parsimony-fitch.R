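#' Fitch parsimony score of a tree
#'
#' Computes tree length and per-character step counts under unordered
#' (Fitch) parsimony.  Characters flagged as ordered are scored by linear
#' dynamic programming with cost `|i - j|` between state ranks (used for
#' the stratigraphic character); all others use Fitch 0/1 costs.
#'
#' Taxa entirely missing for a character (full ambiguity) contribute no
#' steps.  The score is invariant under re-rooting.
#'
#' @param tree a `phylo`; its tips must be a subset of `m`'s taxa.  Taxa
#'   absent from the tree are ignored.
#' @param m a [morph_matrix].
#' @return a list of class `"tree_statistics"` with elements `length`
#'   (weighted total steps) and `per_character_steps`.
#' @examples
#' m <- morph_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' tr <- read_tree(text = "((A,B),(C,D));")
#' fitch_score(tr, m)$length  # 1
#' @export
fitch_score <- function(tree, m) {
  steps <- per_character_steps(tree, m)
  structure(list(length = sum(steps * m$weights),
                 per_character_steps = steps),
            class = "tree_statistics")
}

#' @rdname fitch_score
#' @export
per_character_steps <- function(tree, m) {
  tree <- .prepare_tree(tree, m)
  unord <- !m$ordered
  steps <- numeric(n_char(m))
  if (any(unord))
    steps[unord] <- .fitch_steps(tree, m$masks[, unord, drop = FALSE],
                                 tree$tip.index)
  for (j in which(m$ordered))
    steps[j] <- .sankoff_min(tree, m, j)
  steps
}

# match tips to matrix rows, force binary rooted shape
.prepare_tree <- function(tree, m) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  tree$tip.label <- normalize_labels(tree$tip.label)
  idx <- match(tree$tip.label, m$taxa)
  if (anyNA(idx))
    stop("taxon-mismatch error: tree tip '",
         tree$tip.label[is.na(idx)][1L], "' has no matrix row")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  # root along the first tip's edge if basal polytomy (scores unchanged)
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    tree2 <- tryCatch(ape::multi2di(ape::root(tree, outgroup = tree$tip.label[1L],
                                              resolve.root = TRUE)),
                      error = function(e) NULL)
    if (is.null(tree2) || !ape::is.binary(tree2))
      stop("tree could not be resolved to binary; polytomies beyond the ",
           "root are not scored")
    tree2$tip.label <- normalize_labels(tree2$tip.label)
    tree <- tree2
    idx <- match(tree$tip.label, m$taxa)
  }
  tree <- stats::reorder(tree, "postorder")
  tree$tip.index <- idx
  tree
}

# vectorized Fitch over a bank of unordered characters (bitmask columns)
.fitch_steps <- function(tree, masks, tip.index) {
  nc <- ncol(masks)
  if (nc == 0L) return(numeric(0))
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  state <- matrix(0L, ntip + nnode, nc)
  state[seq_len(ntip), ] <- masks[tip.index, , drop = FALSE]
  steps <- numeric(nc)
  e <- tree$edge
  # postorder: children appear before parents
  for (k in seq(1L, nrow(e), by = 2L)) {
    parent <- e[k, 1L]
    a <- state[e[k, 2L], ]
    b <- state[e[k + 1L, 2L], ]
    inter <- bitwAnd(a, b)
    empty <- inter == 0L
    steps[empty] <- steps[empty] + 1
    inter[empty] <- bitwOr(a, b)[empty]
    state[parent, ] <- inter
  }
  steps
}

# masks -> list of allowed state indices, per taxon, character j
.allowed_states <- function(m, j) {
  k <- length(m$alphabets[[j]])
  lapply(m$masks[, j], function(msk)
    which(bitwAnd(bitwShiftR(msk, seq_len(k) - 1L), 1L) == 1L))
}

# cost matrix for character j: 0/1 (unordered) or |i-j| (ordered)
.char_cost <- function(m, j) {
  k <- length(m$alphabets[[j]])
  if (m$ordered[j]) abs(outer(seq_len(k), seq_len(k), "-"))
  else 1 - diag(k)
}

# Sankoff down-pass cost table for one character; returns matrix
# (nodes x states) of minimal subtree costs.  `constraint` optionally
# restricts the allowed states of one internal node (ADR test).
.sankoff_down <- function(tree, m, j, constraint = NULL) {
  k <- length(m$alphabets[[j]])
  cost <- .char_cost(m, j)
  ntip <- ape::Ntip(tree)
  D <- matrix(Inf, ntip + tree$Nnode, k)
  allowed <- .allowed_states(m, j)
  for (i in seq_len(ntip)) D[i, allowed[[tree$tip.index[i]]]] <- 0
  e <- tree$edge
  done <- logical(ntip + tree$Nnode)
  for (k2 in seq_len(nrow(e))) {
    p <- e[k2, 1L]; ch <- e[k2, 2L]
    contrib <- apply(D[ch, ] + cost, 2L, min)   # cost[s, t] symmetric
    if (!done[p]) { D[p, ] <- contrib; done[p] <- TRUE }
    else D[p, ] <- D[p, ] + contrib
  }
  if (!is.null(constraint)) {
    node <- constraint$node
    D[node, setdiff(seq_len(k), constraint$states)] <- Inf
    # propagate upward again: recompute ancestors of `node`
    anc <- .ancestors(tree, node)
    for (a in anc) {
      kids <- e[e[, 1L] == a, 2L]
      D[a, ] <- 0
      for (ch in kids) D[a, ] <- D[a, ] + apply(D[ch, ] + cost, 2L, min)
    }
  }
  D
}

.sankoff_min <- function(tree, m, j, constraint = NULL) {
  D <- .sankoff_down(tree, m, j, constraint)
  root <- ape::Ntip(tree) + 1L
  min(D[root, ])
}

.ancestors <- function(tree, node) {
  e <- tree$edge
  out <- integer(0)
  cur <- node
  repeat {
    p <- e[e[, 2L] == cur, 1L]
    if (length(p) == 0L) break
    out <- c(out, p)
    cur <- p
  }
  out
}
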