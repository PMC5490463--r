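#' Per-character consistency index on a tree
#'
#' CI of a character = minimum conceivable steps / observed steps on the
#' tree.  Constant characters (zero minimum and zero observed steps)
#' have no defined CI and are returned as `NA` with a flag.
#'
#' @inheritParams fitch_score
#' @return data frame with columns `character`, `min_steps`, `steps`,
#'   `ci` (`NA` for constants), `constant`.
#' @examples
#' m <- morph_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' per_character_ci(read_tree(text = "((A,C),(B,D));"), m)$ci  # 0.5
#' @export
per_character_ci <- function(tree, m) {
  s <- per_character_steps(tree, m)
  mn <- char_min_steps(m)
  ci <- ifelse(s > 0, mn / s, NA_real_)
  data.frame(character = seq_len(n_char(m)), min_steps = mn, steps = s,
             ci = ci, constant = mn == 0)
}

#' Homoplasy screening of characters against reference trees
#'
#' Re-enacts a homoplasy-reduction protocol: each character is mapped on
#' each reference tree (restricted to the taxa the matrix and that tree
#' share) and its per-character CI computed there; characters whose CI
#' falls below `threshold` on any reference tree (`rule = "any"`, the
#' default) or on all of them (`rule = "all"`) are excluded.  Characters
#' that cannot be scored on a tree (constant over the shared taxa, or no
#' data there) yield no verdict from that tree and are retained when no
#' tree produces a verdict, with a warning: absence of evidence of
#' homoplasy is not evidence of homoplasy.
#'
#' @param m a [morph_matrix] of candidate characters.
#' @param reference_trees a `phylo`, `multiPhylo`, or list of `phylo`
#'   objects; tips must map into `m`'s taxa.
#' @param threshold CI below which a character is excluded (default 1,
#'   i.e. any homoplasy excludes).
#' @param rule combine verdicts across trees: fail on `"any"` tree or on
#'   `"all"` trees.
#' @return a list of class `"character_screen"`: `report` (one row per
#'   character x tree: `character`, `tree`, `min_steps`, `steps`, `ci`,
#'   `scorable`), `verdict` (per character: `"retain"`/`"exclude"`),
#'   `matrix` (the retained-character submatrix), `threshold`, `rule`.
#' @export
screen_characters <- function(m, reference_trees, threshold = 1.0,
                              rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (inherits(reference_trees, "phylo"))
    reference_trees <- list(reference_trees)
  report <- list()
  fails <- matrix(NA, n_char(m), length(reference_trees))
  for (t in seq_along(reference_trees)) {
    tr <- reference_trees[[t]]
    tr$tip.label <- normalize_labels(tr$tip.label)
    shared <- intersect(tr$tip.label, m$taxa)
    if (length(shared) == 0L)
      stop("coverage error: reference tree ", t,
           " shares no taxa with the matrix")
    tr <- if (length(shared) < ape::Ntip(tr))
      ape::drop.tip(tr, setdiff(tr$tip.label, shared)) else tr
    sub <- m[shared, ]
    cij <- per_character_ci(tr, sub)
    cij$tree <- t
    cij$scorable <- !is.na(cij$ci)
    report[[t]] <- cij
    fails[cij$scorable, t] <- cij$ci[cij$scorable] < threshold
  }
  verdict_fail <- apply(fails, 1L, function(f) {
    f <- f[!is.na(f)]
    if (!length(f)) NA
    else if (rule == "any") any(f) else all(f)
  })
  unscorable <- is.na(verdict_fail)
  if (any(unscorable))
    warning(sum(unscorable), " character(s) unscorable on every reference ",
            "tree; retained without a homoplasy verdict")
  verdict <- ifelse(!is.na(verdict_fail) & verdict_fail, "exclude", "retain")
  keep <- verdict == "retain"
  report <- do.call(rbind, report)
  report <- report[, c("character", "tree", "min_steps", "steps", "ci",
                       "scorable")]
  structure(list(report = report, verdict = verdict,
                 matrix = m[, keep], threshold = threshold, rule = rule),
            class = "character_screen")
}

#' @export
print.character_screen <- function(x, ...) {
  cat("character screen: ", sum(x$verdict == "retain"), " retained / ",
      sum(x$verdict == "exclude"), " excluded (CI < ", x$threshold,
      " on ", x$rule, " reference tree)\n", sep = "")
  invisible(x)
}
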