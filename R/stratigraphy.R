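#' Stratigraphic range table
#'
#' Per-taxon first (FAD) and last (LAD) appearance ages in Ma, with
#' `fad_ma >= lad_ma >= 0` and unique taxa.  Labels are normalized with
#' [normalize_labels()] so they match matrix and tree labels.
#'
#' @param taxon character vector of taxon labels.
#' @param fad_ma first-appearance ages (Ma).
#' @param lad_ma last-appearance ages (Ma); defaults to `fad_ma` (point
#'   occurrences).
#' @return a data frame of class `"strat_ranges"`.
#' @export
strat_ranges <- function(taxon, fad_ma, lad_ma = fad_ma) {
  taxon <- normalize_labels(taxon)
  if (anyDuplicated(taxon))
    stop("duplicate taxon in range table: ", taxon[duplicated(taxon)][1L])
  fad_ma <- as.numeric(fad_ma); lad_ma <- as.numeric(lad_ma)
  if (any(is.na(fad_ma)) || any(is.na(lad_ma)))
    stop("non-numeric age in range table")
  if (any(lad_ma < 0)) stop("negative age in range table")
  if (any(fad_ma < lad_ma)) stop("FAD must be >= LAD (taxon ",
                                 taxon[fad_ma < lad_ma][1L], ")")
  structure(data.frame(taxon = taxon, fad_ma = fad_ma, lad_ma = lad_ma,
                       stringsAsFactors = FALSE),
            class = c("strat_ranges", "data.frame"))
}

.range_lookup <- function(ranges, taxa) {
  idx <- match(normalize_labels(taxa), ranges$taxon)
  stats::setNames(ranges$fad_ma[idx], taxa)
}

# prune tips without ranges (warn), per the missing-range policy
.prune_undated <- function(tree, ranges) {
  fad <- .range_lookup(ranges, tree$tip.label)
  drop <- tree$tip.label[is.na(fad)]
  if (length(drop)) {
    warning("pruning ", length(drop), " tip(s) without stratigraphic ",
            "ranges: ", paste(drop, collapse = ", "))
    if (ape::Ntip(tree) - length(drop) < 3L)
      stop("fewer than 3 dated tips remain")
    tree <- ape::drop.tip(tree, drop)
  }
  tree
}

#' Oldest first appearance within a clade
#'
#' @param node node id (tip or internal) of `tree`.
#' @param tree a rooted `phylo`.
#' @param ranges a [strat_ranges()] table covering the tips below `node`.
#' @return the maximum FAD (Ma) over descendant tips with data.
#' @export
clade_fad <- function(node, tree, ranges) {
  tips <- if (node <= ape::Ntip(tree)) tree$tip.label[node]
          else .tips_below(tree, node)
  fad <- .range_lookup(ranges, tips)
  fad <- fad[!is.na(fad)]
  if (!length(fad))
    stop("undatable-node error: no dated tip below node ", node)
  max(fad)
}

#' Stratigraphic consistency index
#'
#' Following the standard formulation, an internal non-root node is
#' *stratigraphically consistent* when the oldest first appearance in its
#' clade is not older than the oldest first appearance in its sister
#' clade (ties count as consistent).  The SCI is the number of consistent
#' nodes divided by the number of evaluated nodes: internal nodes
#' excluding the root, skipping nodes without a defined verdict.  For a
#' fully dichotomous rooted tree with n tips this denominator is n - 2.
#'
#' Tips without ranges are pruned first with a warning.
#'
#' @param tree a rooted `phylo`.
#' @param ranges a [strat_ranges()] table.
#' @return a list of class `"sci_result"`: `sci`, `consistent`,
#'   `evaluated`, and `verdicts` (data frame with per-node clade/sister
#'   FADs and verdicts).
#' @examples
#' tr <- read_tree(text = "(((A,B),C),D);")
#' rg <- strat_ranges(c("A", "B", "C", "D"), c(1, 2, 3, 4))
#' sci(tr, rg)$sci  # 1
#' @export
sci <- function(tree, ranges) {
  if (!ape::is.rooted(tree))
    stop("rooting-required error: SCI needs a rooted tree")
  tree$tip.label <- normalize_labels(tree$tip.label)
  tree <- .prune_undated(tree, ranges)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- .children(tree)
  par <- .parents(tree)
  internal <- setdiff(unique(tree$edge[, 1L]), root)
  rows <- lapply(sort(internal), function(v) {
    sibs <- setdiff(kids[[par[v]]], v)
    own <- tryCatch(clade_fad(v, tree, ranges), error = function(e) NA_real_)
    sis <- suppressWarnings(max(vapply(sibs, function(w)
      tryCatch(clade_fad(w, tree, ranges), error = function(e) -Inf),
      numeric(1))))
    data.frame(node = v, clade_fad = own,
               sister_fad = if (is.finite(sis)) sis else NA_real_)
  })
  verdicts <- do.call(rbind, rows)
  verdicts$consistent <- verdicts$clade_fad <= verdicts$sister_fad
  ok <- !is.na(verdicts$consistent)
  consistent <- sum(verdicts$consistent[ok])
  evaluated <- sum(ok)
  if (evaluated == 0L) stop("no evaluable internal nodes")
  structure(list(sci = consistent / evaluated, consistent = consistent,
                 evaluated = evaluated, verdicts = verdicts),
            class = "sci_result")
}

#' @export
print.sci_result <- function(x, ...) {
  cat(sprintf("SCI = %d/%d = %.3f\n", x$consistent, x$evaluated, x$sci))
  invisible(x)
}

#' Fossil-constrained minimum divergence dates and ghost lineages
#'
#' Each internal node's minimum age is the oldest first appearance among
#' its descendant tips.  The ghost-lineage duration on a branch is the
#' parent's minimum age minus the child's clade FAD (zero on the branch
#' carrying the oldest child).
#'
#' @inheritParams sci
#' @param clades optional named list of taxon-label vectors; the minimum
#'   origin age of the most recent common ancestor of each set is
#'   reported.
#' @return a list of class `"divergence_estimate"`: `node_ages` (data
#'   frame `node`, `min_age_ma`), `ghosts` (data frame `parent`, `child`,
#'   `ghost_myr`), `clade_ages` (named numeric, when `clades` given),
#'   `total_ghost_myr`.
#' @export
min_divergence_dates <- function(tree, ranges, clades = NULL) {
  if (!ape::is.rooted(tree))
    stop("rooting-required error: dating needs a rooted tree")
  tree$tip.label <- normalize_labels(tree$tip.label)
  tree <- .prune_undated(tree, ranges)
  internal <- sort(unique(tree$edge[, 1L]))
  ages <- vapply(internal, clade_fad, numeric(1), tree = tree,
                 ranges = ranges)
  node_ages <- data.frame(node = internal, min_age_ma = ages)
  age_of <- function(v) {
    if (v <= ape::Ntip(tree)) .range_lookup(ranges, tree$tip.label[v])
    else ages[match(v, internal)]
  }
  ghosts <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L])
  ghosts$ghost_myr <- vapply(seq_len(nrow(ghosts)), function(k)
    age_of(ghosts$parent[k]) - age_of(ghosts$child[k]), numeric(1))
  clade_ages <- NULL
  if (!is.null(clades)) {
    clade_ages <- vapply(clades, function(tips) {
      tips <- intersect(normalize_labels(tips), tree$tip.label)
      if (length(tips) < 2L) return(NA_real_)
      clade_fad(ape::getMRCA(tree, tips), tree, ranges)
    }, numeric(1))
  }
  structure(list(node_ages = node_ages, ghosts = ghosts,
                 clade_ages = clade_ages,
                 total_ghost_myr = sum(ghosts$ghost_myr)),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat("minimum divergence dates:", nrow(x$node_ages), "nodes; total ghost",
      sprintf("%.2f Myr\n", x$total_ghost_myr))
  invisible(x)
}
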