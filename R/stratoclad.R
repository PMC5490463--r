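#' Default geological-stage time bins
#'
#' Late Neogene stage bins (ordered old to young) used by default for
#' the stratigraphic character: Tortonian, Messinian, Zanclean,
#' Piacenzian, and a terminal Gelasian-to-Recent bin.  Ages in Ma.
#' These bins are a reconstruction of common stage-level practice;
#' analyses with other faunas should supply their own bins.
#'
#' @return data frame with columns `bin`, `older_ma`, `younger_ma`.
#' @export
stage_bins <- function() {
  data.frame(bin = c("Tortonian", "Messinian", "Zanclean", "Piacenzian",
                     "Gelasian+"),
             older_ma = c(11.63, 7.246, 5.333, 3.6, 2.58),
             younger_ma = c(7.246, 5.333, 3.6, 2.58, 0))
}

.check_bins <- function(bins) {
  stopifnot(all(c("bin", "older_ma", "younger_ma") %in% names(bins)))
  if (any(bins$older_ma <= bins$younger_ma))
    stop("each bin must have older_ma > younger_ma")
  if (nrow(bins) > 1L &&
      any(abs(bins$older_ma[-1L] - bins$younger_ma[-nrow(bins)]) > 1e-9))
    stop("bins must be contiguous and ordered old to young")
  bins
}

#' Build an ordered stratigraphic character from fossil ranges
#'
#' Each taxon's state is the index of the time bin containing its first
#' appearance (FAD); the character is *ordered*, so the parsimony cost of
#' a change from bin i to bin j is |i - j|.  Taxa missing from the range
#' table become fully ambiguous.
#'
#' @param ranges a [strat_ranges()] table.
#' @param bins bin table as from [stage_bins()], ordered old to young.
#' @param taxa taxa (and row order) of the resulting column; defaults to
#'   `ranges$taxon`.
#' @return a one-character [morph_matrix] (ordered), with bin names kept
#'   in `attr(, "bins")`.
#' @examples
#' rg <- strat_ranges(c("A", "B"), c(6, 3))
#' build_strat_character(rg)  # Messinian vs Piacenzian bins
#' @export
build_strat_character <- function(ranges, bins = stage_bins(),
                                  taxa = ranges$taxon) {
  bins <- .check_bins(bins)
  taxa <- normalize_labels(taxa)
  fad <- .range_lookup(ranges, taxa)
  state <- character(length(taxa))
  for (i in seq_along(taxa)) {
    if (is.na(fad[i])) { state[i] <- "?"; next }
    hit <- which(fad[i] <= bins$older_ma & fad[i] >= bins$younger_ma)
    if (!length(hit))
      stop("binning error: FAD ", fad[i], " Ma of taxon '", taxa[i],
           "' falls outside the bin coverage")
    state[i] <- as.character(min(hit) - 1L)  # oldest matching bin, 0-based
  }
  cells <- matrix(state, ncol = 1L, dimnames = list(taxa, NULL))
  out <- morph_matrix(cells, taxa = taxa, ordered = TRUE,
                      alphabets = list(as.character(seq_len(nrow(bins)) - 1L)))
  attr(out, "bins") <- bins
  out
}

#' Append a stratigraphic character to a matrix
#'
#' @param m a [morph_matrix].
#' @inheritParams build_strat_character
#' @return `m` with one extra ordered character (the last column).
#' @export
add_strat_character <- function(m, ranges, bins = stage_bins()) {
  sc <- build_strat_character(ranges, bins, taxa = m$taxa)
  structure(list(taxa = m$taxa,
                 masks = cbind(m$masks, sc$masks),
                 alphabets = c(m$alphabets, sc$alphabets),
                 ordered = c(m$ordered, TRUE),
                 weights = c(m$weights, 1)),
            class = "morph_matrix")
}

#' Ancestor-descendant hypothesis
#'
#' @param ancestor taxon label of the putative ancestor (a tip of the
#'   tree under test).
#' @param descendant taxon label, or character vector of labels for a
#'   descendant clade.
#' @return a list of class `"adr_hypothesis"`.
#' @export
adr_hypothesis <- function(ancestor, descendant) {
  ancestor <- normalize_labels(ancestor)
  descendant <- normalize_labels(descendant)
  if (ancestor %in% descendant)
    stop("hypothesis error: ancestor and descendant must be distinct")
  structure(list(ancestor = ancestor, descendant = descendant),
            class = "adr_hypothesis")
}

#' Tree length under an ancestor-descendant hypothesis
#'
#' Scores the hypothesis that `ancestor` is the direct ancestor of
#' `descendant` rather than its sister: the ancestor tip is removed from
#' the tree and its observed (non-missing) states are fixed as
#' constraints at the internal node from which the descendant (tip or
#' clade) descends -- the MacClade-style "ancestorization" of a terminal
#' with a zero-length attachment.  Characters for which the ancestor is
#' missing leave that node unconstrained.
#'
#' @param tree a rooted `phylo` containing both hypothesis taxa.
#' @param m a [morph_matrix]; ordered characters (e.g. the stratigraphic
#'   character from [add_strat_character()]) are costed linearly.
#' @param hypothesis an [adr_hypothesis()].
#' @return a list of class `"adr_score"`: `length` (total),
#'   `morphology_length`, `strat_length` (cost of ordered characters, 0
#'   when none), `per_character_steps`, `pruned_tree`, `constrained_node`.
#' @export
adr_score <- function(tree, m, hypothesis) {
  stopifnot(inherits(hypothesis, "adr_hypothesis"))
  tree$tip.label <- normalize_labels(tree$tip.label)
  anc <- hypothesis$ancestor
  des <- hypothesis$descendant
  if (!(anc %in% tree$tip.label))
    stop("ancestor '", anc, "' is not a tip of the tree")
  if (!all(des %in% tree$tip.label))
    stop("descendant taxa missing from tree: ",
         paste(setdiff(des, tree$tip.label), collapse = ", "))
  pruned <- ape::drop.tip(tree, anc)
  ptree <- .prepare_tree(pruned, m)
  node <- if (length(des) == 1L)
    .parents(ptree)[match(des, ptree$tip.label)]
  else ape::getMRCA(ptree, des)
  anc_row <- match(anc, m$taxa)
  if (is.na(anc_row)) stop("ancestor '", anc, "' has no matrix row")
  miss <- .missing_cells(m)[anc_row, ]
  steps <- numeric(n_char(m))
  for (j in seq_len(n_char(m))) {
    constraint <- if (miss[j]) NULL else {
      k <- length(m$alphabets[[j]])
      list(node = node,
           states = which(bitwAnd(bitwShiftR(m$masks[anc_row, j],
                                             seq_len(k) - 1L), 1L) == 1L))
    }
    steps[j] <- .sankoff_min(ptree, m, j, constraint)
  }
  total <- sum(steps * m$weights)
  strat <- sum(steps[m$ordered] * m$weights[m$ordered])
  structure(list(length = total, morphology_length = total - strat,
                 strat_length = strat, per_character_steps = steps,
                 pruned_tree = pruned, constrained_node = node),
            class = "adr_score")
}

#' @export
print.adr_score <- function(x, ...) {
  cat("ADR length:", x$length, "( morphology", x$morphology_length,
      "+ stratigraphic", x$strat_length, ")\n")
  invisible(x)
}

#' Compare ancestor-descendant vs sister-group hypotheses
#'
#' Computes the parsimony *debt* of ancestorizing a terminal: the tree
#' length under the ancestor-descendant constraint ([adr_score()]) minus
#' the length of the unmodified tree with the ancestor as a sister tip.
#' The comparison is reported both on morphology alone and, when
#' `ranges` are supplied, with an ordered stratigraphic character
#' appended ([add_strat_character()]), as stratocladistic practice folds
#' stratigraphic misfit into tree length.
#'
#' @inheritParams adr_score
#' @param ranges optional [strat_ranges()]; enables the with-character
#'   comparison.
#' @param bins bins for the stratigraphic character (default
#'   [stage_bins()]).
#' @param alternative optional user-supplied topology (`phylo`) to score
#'   alongside (branch swapping "by hand").
#' @return a list of class `"adr_comparison"` with sister/ADR lengths
#'   and debts without and (when available) with the stratigraphic
#'   character, the shorter hypothesis under each mode, and the
#'   alternative-topology scores when requested.
#' @export
compare_adr <- function(tree, m, hypothesis, ranges = NULL,
                        bins = stage_bins(), alternative = NULL) {
  sister_len <- fitch_score(tree, m)$length
  adr <- adr_score(tree, m, hypothesis)
  debt_morph <- adr$length - sister_len
  out <- list(sister_length = sister_len, adr_length = adr$length,
              debt_morphology = debt_morph,
              verdict_morphology = if (debt_morph > 0) "sister-group"
                                   else if (debt_morph < 0) "ADR" else "tie")
  if (!is.null(ranges)) {
    ms <- add_strat_character(m, ranges, bins)
    sister_s <- fitch_score(tree, ms)$length
    adr_s <- adr_score(tree, ms, hypothesis)
    debt_s <- adr_s$length - sister_s
    out$sister_length_strat <- sister_s
    out$adr_length_strat <- adr_s$length
    out$debt_with_strat <- debt_s
    out$verdict_with_strat <- if (debt_s > 0) "sister-group"
                              else if (debt_s < 0) "ADR" else "tie"
  }
  if (!is.null(alternative)) {
    out$alternative_sister_length <- fitch_score(alternative, m)$length
    out$alternative_adr_length <- adr_score(alternative, m, hypothesis)$length
  }
  structure(out, class = "adr_comparison")
}

#' @export
print.adr_comparison <- function(x, ...) {
  cat("ADR test: sister length", x$sister_length, "| ADR length",
      x$adr_length, "| debt", x$debt_morphology,
      "->", x$verdict_morphology, "\n")
  if (!is.null(x$debt_with_strat))
    cat("  with stratigraphic character: debt", x$debt_with_strat, "->",
        x$verdict_with_strat, "\n")
  invisible(x)
}
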