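#' Ensemble tree statistics (CI, RI, RC, HI)
#'
#' Scores a tree against a matrix and reports tree length, per-character
#' steps, and the ensemble consistency index (CI = M/S), retention index
#' (RI = (G-S)/(G-M)), rescaled consistency index (RC = CI*RI) and
#' homoplasy index (HI = 1-CI), where per character:
#'
#' * `m` (minimum steps) = number of observed states minus one, over taxa
#'   with data;
#' * `s` (observed steps) = Fitch steps on the tree;
#' * `g` (maximum steps on any tree) = number of determinate cells minus
#'   the count of the most frequent state.
#'
#' Parsimony-uninformative characters (those with `g == m`, i.e. constant
#' or autapomorphic) are always excluded from the RI sums; whether they
#' enter the CI sums is controlled by `include_uninformative` (the TNT
#' convention includes them, which lowers the ensemble CI).  The chosen
#' convention is recorded in the result.
#'
#' @inheritParams fitch_score
#' @param include_uninformative include parsimony-uninformative
#'   characters in the CI sums (default `TRUE`, TNT convention).
#' @return a `"tree_statistics"` list: `length`, `per_character_steps`,
#'   `min_steps`, `max_steps`, `ci`, `ri`, `rc`, `hi`,
#'   `include_uninformative`.
#' @examples
#' m <- morph_matrix(rbind(A = "0", B = "1", C = "0", D = "1"))
#' tr <- read_tree(text = "((A,C),(B,D));")
#' tree_statistics(tr, m)$ci  # 1
#' @export
tree_statistics <- function(tree, m, include_uninformative = TRUE) {
  if (n_char(m) == 0L)
    stop("undefined-statistics error: matrix has no characters")
  s <- per_character_steps(tree, m)
  mn <- char_min_steps(m)
  g <- char_max_steps(m)
  w <- m$weights

  informative <- g > mn
  ci_keep <- if (include_uninformative) rep(TRUE, n_char(m)) else informative
  S <- sum(w[ci_keep] * s[ci_keep])
  M <- sum(w[ci_keep] * mn[ci_keep])
  if (S == 0)
    stop("undefined-statistics error: tree length is zero")
  ci <- M / S
  Sg <- sum(w[informative] * s[informative])
  Mg <- sum(w[informative] * mn[informative])
  G <- sum(w[informative] * g[informative])
  ri <- if (G > Mg) (G - Sg) / (G - Mg) else NA_real_
  structure(list(length = sum(w * s), per_character_steps = s,
                 min_steps = mn, max_steps = g,
                 ci = ci, ri = ri, rc = ci * ri, hi = 1 - ci,
                 include_uninformative = include_uninformative),
            class = "tree_statistics")
}

#' @export
print.tree_statistics <- function(x, ...) {
  cat("tree length:", x$length, "\n")
  if (!is.null(x$ci)) {
    cat(sprintf("  CI %.4f  RI %.4f  RC %.5f  HI %.4f\n",
                x$ci, x$ri, x$rc, x$hi))
    cat("  uninformative characters in CI sums:",
        x$include_uninformative, "\n")
  }
  invisible(x)
}

#' Per-character minimum and maximum conceivable steps
#'
#' `char_min_steps` returns, per character, the number of observed states
#' minus one (observed = union of states over cells that are not fully
#' ambiguous).  For ordered characters it is the range of observed state
#' ranks.  `char_max_steps` returns the maximum steps attainable on any
#' tree (for unordered characters: determinate cells minus the modal
#' state count; ambiguous cells are left out of both counts).
#'
#' @param m a [morph_matrix].
#' @return numeric vector, one value per character.
#' @export
char_min_steps <- function(m) {
  miss <- .missing_cells(m)
  vapply(seq_len(n_char(m)), function(j) {
    obs <- Reduce(bitwOr, m$masks[!miss[, j], j], accumulate = FALSE)
    if (is.null(obs) || length(obs) == 0L) return(0)
    k <- length(m$alphabets[[j]])
    bits <- which(bitwAnd(bitwShiftR(obs, seq_len(k) - 1L), 1L) == 1L)
    if (length(bits) == 0L) return(0)
    if (m$ordered[j]) max(bits) - min(bits) else length(bits) - 1
  }, numeric(1))
}

#' @rdname char_min_steps
#' @export
char_max_steps <- function(m) {
  vapply(seq_len(n_char(m)), function(j) {
    k <- length(m$alphabets[[j]])
    det <- m$masks[, j][.popcount(m$masks[, j]) == 1L]
    if (length(det) == 0L) return(0)
    freq <- tabulate(round(log2(det)) + 1L, nbins = k)
    if (m$ordered[j]) {
      # ordered worst case: star tree cost from the cheapest hub state
      ranks <- rep(seq_len(k), freq)
      min(vapply(seq_len(k), function(s) sum(abs(ranks - s)), numeric(1)))
    } else length(det) - max(freq)
  }, numeric(1))
}

.popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}
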