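#' ACCTRAN ancestral-state optimization and synapomorphy mapping
#'
#' Assigns a single state per node and character achieving the Fitch
#' (or ordered, for ordered characters) minimum length, under accelerated
#' transformation: changes are pulled as close to the root as the optimum
#' permits.  Operationally, states are chosen root-to-tips by dynamic
#' programming; when several states tie for the minimal total cost at an
#' internal node, a state *differing* from the parent's is preferred
#' (taking the change on the current branch rather than deferring it),
#' and remaining ties are broken by the lexicographically smallest state
#' symbol.  The root state is the lexicographically smallest state of the
#' optimal set.  These tie-break rules are recorded in the result.
#'
#' @param tree a rooted binary `phylo` over (a subset of) `m`'s taxa.
#' @param m a [morph_matrix].
#' @return a list of class `"acctran_map"`:
#'   * `states`: character matrix (nodes x characters) of assigned symbols;
#'   * `changes`: data frame with one row per state change (`node` = child
#'     end of the branch, `character`, `from`, `to`, `at_tip`, `ambiguity`);
#'   * `synapomorphies`: the subset of `changes` at internal nodes;
#'   * `tree`: the (postorder) tree scored, with `tip.index` mapping.
#'
#' The per-character number of rows in `changes` equals that character's
#' step count, so `nrow(changes)` is the tree length.
#' @examples
#' m <- morph_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' tr <- read_tree(text = "((A,B),(C,D));")
#' acctran_optimize(tr, m)$changes
#' @export
acctran_optimize <- function(tree, m) {
  if (!ape::is.rooted(tree))
    stop("rooting-required error: ACCTRAN needs a rooted tree")
  tree <- .prepare_tree(tree, m)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  kids <- .children(tree)
  par <- .parents(tree)
  states <- matrix(NA_character_, nnode, n_char(m))
  changes <- list()
  for (j in seq_len(n_char(m))) {
    alpha <- m$alphabets[[j]]
    cost <- .char_cost(m, j)
    D <- .sankoff_down(tree, m, j)
    assign_state <- integer(nnode)
    # preorder walk
    ord <- c(root, rev(tree$edge[, 2L]))  # postorder reversed = preorder
    for (v in ord) {
      if (v == root) {
        opt <- which(D[root, ] == min(D[root, ]))
        assign_state[v] <- opt[1L]  # alphabet sorted: smallest symbol
        next
      }
      a <- assign_state[par[v]]
      tot <- D[v, ] + cost[a, ]
      opt <- which(tot == min(tot))
      if (length(opt) > 1L) {
        differing <- opt[opt != a]
        opt <- if (length(differing)) differing else opt
      }
      assign_state[v] <- opt[1L]
    }
    states[, j] <- alpha[assign_state]
    nonroot <- which(par != 0L)
    changed <- nonroot[assign_state[par[nonroot]] != assign_state[nonroot]]
    if (length(changed)) {
      changes[[length(changes) + 1L]] <- data.frame(
        node = changed,
        character = j,
        from = alpha[assign_state[par[changed]]],
        to = alpha[assign_state[changed]],
        at_tip = changed <= ntip,
        stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes)
             else data.frame(node = integer(0), character = integer(0),
                             from = character(0), to = character(0),
                             at_tip = logical(0))
  changes <- changes[order(changes$character, changes$node), , drop = FALSE]
  rownames(changes) <- NULL
  syn <- changes[!changes$at_tip, , drop = FALSE]
  if (nrow(syn)) {
    amb <- character(nrow(syn))
    for (j in unique(syn$character)) {
      io <- .inside_outside(tree, m, j)
      rows <- which(syn$character == j)
      amb[rows] <- vapply(syn$node[rows], .classify_edge, character(1),
                          io = io)
    }
    syn$ambiguity <- amb
  } else syn$ambiguity <- character(0)
  rownames(syn) <- NULL
  structure(list(states = states, changes = changes, synapomorphies = syn,
                 tree = tree),
            class = "acctran_map")
}

#' @export
print.acctran_map <- function(x, ...) {
  cat("ACCTRAN optimization:", nrow(x$changes), "changes (",
      sum(!x$changes$at_tip), "at internal nodes )\n")
  invisible(x)
}

#' Classify a synapomorphy as ambiguous or unambiguous
#'
#' A change placed by ACCTRAN on the branch subtending `node` for
#' `character` is *unambiguous* when every most-parsimonious
#' reconstruction has a change on that branch and assigns the same
#' derived state at `node`; otherwise it is *ambiguous*.  Decided
#' exactly by inside/outside dynamic programming (no enumeration).
#'
#' @param node internal node id (as in the postorder tree returned by
#'   [acctran_optimize()]).
#' @param character character index.
#' @inheritParams acctran_optimize
#' @param .checked internal; skip re-verification that a change exists.
#' @return `"unambiguous"` or `"ambiguous"`.
#' @export
classify_synapomorphy <- function(node, character, tree, m,
                                  .checked = FALSE) {
  if (!.checked) {
    tree <- .prepare_tree(tree, m)
    map <- acctran_optimize(tree, m)
    hit <- map$changes$node == node & map$changes$character == character
    if (!any(hit))
      stop("no-synapomorphy error: ACCTRAN places no change of character ",
           character, " at node ", node)
    tree <- map$tree
  }
  io <- .inside_outside(tree, m, character)
  .classify_edge(node, io)
}

.classify_edge <- function(node, io) {
  # forced change: every optimal reconstruction changes on this branch.
  # A degree-2 root is a point on the branch joining its two children,
  # so for a root child the branch runs through the root to the sibling.
  sib <- NULL
  if (io$par[node] == io$root && length(io$kids[[io$root]]) == 2L)
    sib <- setdiff(io$kids[[io$root]], node)
  same_state_best <- if (!is.null(sib))
    min(io$D[node, ] + io$D[sib, ])
  else min(io$R[node, ] + io$D[node, ])
  forced <- same_state_best > io$minlen
  # forced derived state: unique optimal state at `node`
  tot <- vapply(seq_len(ncol(io$D)), function(s)
    min(io$R[node, ] + io$cost[, s]) + io$D[node, s], numeric(1))
  unique_state <- sum(tot == io$minlen) == 1L
  if (forced && unique_state) "unambiguous" else "ambiguous"
}

# inside (D) and outside (R) cost tables for one character.
# R[v, t] = minimal cost of the whole tree outside the subtree of v,
# given that v's PARENT has state t (edge (parent,v) not included).
.inside_outside <- function(tree, m, j) {
  cost <- .char_cost(m, j)
  k <- ncol(cost)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  D <- .sankoff_down(tree, m, j)
  kids <- .children(tree)
  R <- matrix(NA_real_, nnode, k)
  # preorder: parent before children
  U <- matrix(Inf, nnode, k)  # U[v, s]: cost outside subtree v, v has state s
  U[root, ] <- 0
  ord <- rev(tree$edge[, 2L])
  par <- .parents(tree)
  for (v in ord) {
    u <- par[v]
    sibs <- setdiff(kids[[u]], v)
    Rv <- U[u, ]
    for (w in sibs) Rv <- Rv + apply(D[w, ] + cost, 2L, min)
    R[v, ] <- Rv
    U[v, ] <- vapply(seq_len(k), function(s) min(Rv + cost[, s]), numeric(1))
  }
  minlen <- min(D[root, ])
  list(D = D, R = R, U = U, cost = cost, minlen = minlen,
       par = par, kids = kids, root = root)
}
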