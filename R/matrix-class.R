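#' Discrete morphological character matrix
#'
#' `morph_matrix()` builds the central data container of paleoclad: an
#' ordered set of taxa scored for discrete, unordered, single-symbol
#' characters.  Cells hold *state sets*: a determinate observation is a
#' one-element set, a polymorphic/uncertain cell (`{01}` in TNT, `(01)` in
#' NEXUS) is a multi-element set, and missing (`?`) or inapplicable (`-`)
#' observations are the full state set of that character (full ambiguity).
#'
#' Internally each cell is an integer bitmask over the character's state
#' alphabet; user-facing accessors translate back to symbol sets.
#'
#' @param cells a list-matrix or character matrix (taxa in rows, characters
#'   in columns).  Character entries may be a single symbol (`"1"`), several
#'   symbols (`"01"`, polymorphic), `"?"` or `"-"` (full ambiguity).
#'   List entries may be character vectors of symbols.
#' @param taxa taxon labels; defaults to `rownames(cells)`.
#' @param ordered logical vector, one per character; `FALSE` (unordered,
#'   Fitch costs) is the default for every character.
#' @param weights non-negative numeric vector of character weights,
#'   default 1.
#' @param alphabets optional list of per-character state alphabets
#'   (character vectors of single symbols, ordered).  When omitted the
#'   alphabet of a character is the sorted set of its observed symbols.
#'
#' @return an object of class `"morph_matrix"` with fields `taxa`,
#'   `masks` (integer bitmask matrix), `alphabets`, `ordered`, `weights`.
#' @examples
#' m <- morph_matrix(rbind(A = c("0", "0"), B = c("1", "?")))
#' m
#' matrix_cells(m)
#' @export
morph_matrix <- function(cells, taxa = rownames(cells), ordered = NULL,
                         weights = NULL, alphabets = NULL) {
  if (is.matrix(cells) && is.character(cells)) {
    cells <- matrix(lapply(cells, .split_symbols), nrow = nrow(cells),
                    dimnames = dimnames(cells))
  }
  if (!is.matrix(cells) || !is.list(cells))
    stop("`cells` must be a character matrix or a list-matrix")
  ntax <- nrow(cells)
  nchar <- ncol(cells)
  if (is.null(taxa)) stop("taxon labels are required")
  taxa <- normalize_labels(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon label: ",
                                taxa[duplicated(taxa)][1L])
  if (any(!nzchar(taxa))) stop("empty taxon label")
  if (length(taxa) != ntax)
    stop("number of labels (", length(taxa), ") != number of rows (",
         ntax, ")")

  if (is.null(alphabets)) {
    alphabets <- lapply(seq_len(nchar), function(j) {
      obs <- sort(unique(unlist(cells[, j])))
      obs <- setdiff(obs, c("?", "-"))
      if (length(obs) == 0L) obs <- "0"  # all-missing character
      obs
    })
  }
  if (length(alphabets) != nchar) stop("one alphabet per character required")

  masks <- matrix(0L, ntax, nchar)
  for (j in seq_len(nchar)) {
    alpha <- alphabets[[j]]
    if (length(alpha) > 30L) stop("state alphabet too large (character ", j, ")")
    full <- sum(bitwShiftL(1L, seq_along(alpha) - 1L))
    for (i in seq_len(ntax)) {
      sym <- cells[[i, j]]
      if (length(sym) == 0L || any(sym %in% c("?", "-"))) {
        masks[i, j] <- full
        next
      }
      idx <- match(sym, alpha)
      if (anyNA(idx))
        stop("unknown state symbol '", sym[is.na(idx)][1L],
             "' for taxon '", taxa[i], "', character ", j)
      masks[i, j] <- sum(bitwShiftL(1L, unique(idx) - 1L))
    }
  }

  if (is.null(ordered)) ordered <- rep(FALSE, nchar)
  if (is.null(weights)) weights <- rep(1, nchar)
  stopifnot(length(ordered) == nchar, length(weights) == nchar,
            all(weights >= 0))
  structure(list(taxa = taxa, masks = masks, alphabets = alphabets,
                 ordered = as.logical(ordered), weights = as.numeric(weights)),
            class = "morph_matrix")
}

.split_symbols <- function(s) {
  if (is.na(s)) return("?")
  strsplit(s, "", fixed = TRUE)[[1L]]
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat("morph_matrix: ", n_taxa(x), " taxa x ", n_char(x), " characters\n",
      sep = "")
  ord <- sum(x$ordered)
  if (ord > 0L) cat("  ordered characters: ", ord, "\n", sep = "")
  show <- utils::head(x$taxa, 8L)
  for (t in show) cat("  ", t, "\n", sep = "")
  if (n_taxa(x) > 8L) cat("  ... and ", n_taxa(x) - 8L, " more taxa\n", sep = "")
  invisible(x)
}

#' @rdname morph_matrix
#' @param m a `morph_matrix`.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname morph_matrix
#' @export
n_char <- function(m) ncol(m$masks)

#' Cells of a matrix as symbol sets
#'
#' @param m a `morph_matrix`.
#' @return a list-matrix whose `[i, j]` entry is the character vector of
#'   state symbols in taxon `i`'s cell for character `j`; a cell equal to
#'   the character's whole alphabet denotes missing/full ambiguity.
#' @export
matrix_cells <- function(m) {
  out <- matrix(vector("list", n_taxa(m) * n_char(m)), nrow = n_taxa(m),
                dimnames = list(m$taxa, NULL))
  for (j in seq_len(n_char(m))) {
    alpha <- m$alphabets[[j]]
    for (i in seq_len(n_taxa(m)))
      out[[i, j]] <- alpha[bitwAnd(bitwShiftR(m$masks[i, j],
                                              seq_along(alpha) - 1L), 1L) == 1L]
  }
  out
}

#' Subset a morphological matrix
#'
#' @param x a `morph_matrix`.
#' @param i taxon selector (names, indices or logical).
#' @param j character selector (indices or logical).
#' @param ... unused.
#' @param drop ignored; the result is always a `morph_matrix`.
#' @export
`[.morph_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(n_taxa(x))
  if (missing(j)) j <- seq_len(n_char(x))
  if (is.character(i)) i <- match(normalize_labels(i), x$taxa)
  if (anyNA(i)) stop("unknown taxon in subset")
  if (is.logical(j)) j <- which(j)
  structure(list(taxa = x$taxa[i],
                 masks = x$masks[i, j, drop = FALSE],
                 alphabets = x$alphabets[j],
                 ordered = x$ordered[j],
                 weights = x$weights[j]),
            class = "morph_matrix")
}

#' Test two matrices for cell-for-cell equality
#'
#' Compares taxa, per-character alphabets and every cell's state set.
#'
#' @param a,b `morph_matrix` objects.
#' @return `TRUE` or `FALSE`.
#' @export
matrix_identical <- function(a, b) {
  identical(a$taxa, b$taxa) &&
    identical(a$alphabets, b$alphabets) &&
    identical(a$masks, b$masks)
}

#' Normalize taxon labels
#'
#' Trims surrounding whitespace and collapses internal runs of whitespace
#' and underscores to a single underscore, so that labels match exactly
#' across matrices, trees and stratigraphic range tables.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalize_labels <- function(x) {
  x <- gsub("^[[:space:]]+|[[:space:]]+$", "", x)
  gsub("[[:space:]_]+", "_", x)
}

# full-ambiguity bitmask for character j
.full_mask <- function(m, j) {
  sum(bitwShiftL(1L, seq_along(m$alphabets[[j]]) - 1L))
}

# TRUE where cell is full ambiguity (missing) for its character
.missing_cells <- function(m) {
  fulls <- vapply(seq_len(n_char(m)), function(j) .full_mask(m, j), integer(1))
  sweep(m$masks, 2L, fulls, `==`)
}
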