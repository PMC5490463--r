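# seed bookkeeping so user-facing simulators/searches are reproducible
# without clobbering the caller's RNG stream
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

# parent lookup: parent[v] = parent node of v (0 for root)
.parents <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# children lookup as a list indexed by node id
.children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  out <- vector("list", n)
  for (k in seq_len(nrow(tree$edge)))
    out[[tree$edge[k, 1L]]] <- c(out[[tree$edge[k, 1L]]], tree$edge[k, 2L])
  out
}
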