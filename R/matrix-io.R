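#' Read a morphological character matrix
#'
#' Reads a discrete character matrix from a NEXUS `DATA`/`CHARACTERS`
#' block (via ape) or a TNT/Hennig86-style `xread` block.  Polymorphic
#' cells (`{01}`, `[01]`, `(01)`) become multi-state sets; `?` and `-`
#' become full ambiguity over the character's alphabet.
#'
#' @param file path to the matrix file, or a character vector of lines
#'   when `text = TRUE`.
#' @param dialect `"nexus"` or `"tnt"`; default guesses from content.
#' @param text logical; treat `file` as literal text lines.
#' @return a [morph_matrix].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(file, dialect = c("auto", "nexus", "tnt"),
                        text = FALSE) {
  dialect <- match.arg(dialect)
  lines <- if (text) unlist(strsplit(file, "\n", fixed = TRUE))
           else readLines(file, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("#NEXUS", lines, ignore.case = TRUE)))
      "nexus" else "tnt"
  }
  switch(dialect, nexus = .read_nexus_matrix(lines),
         tnt = .read_tnt_matrix(lines))
}

.read_nexus_matrix <- function(lines) {
  tf <- tempfile(fileext = ".nex")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  dat <- tryCatch(ape::read.nexus.data(tf),
                  error = function(e) stop("NEXUS parse error: ",
                                           conditionMessage(e), call. = FALSE))
  taxa <- names(dat)
  nchars <- unique(lengths(dat))
  if (length(nchars) != 1L)
    stop("dimension error: taxa score different numbers of characters (",
         paste(nchars, collapse = ", "), ")")
  cells <- matrix(vector("list", length(taxa) * nchars), nrow = length(taxa),
                  dimnames = list(taxa, NULL))
  for (i in seq_along(taxa)) {
    row <- dat[[i]]
    for (j in seq_len(nchars)) {
      # read.nexus.data renders polymorphism as "0/1"
      cells[[i, j]] <- unlist(strsplit(row[j], "/", fixed = TRUE))
    }
  }
  morph_matrix(cells, taxa = taxa)
}

# TNT xread: "xread [comment] nchar ntax  name states  name states ... ;"
.read_tnt_matrix <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("'[^']*'", " ", txt)         # quoted comments
  if (!grepl("xread", txt, ignore.case = TRUE))
    stop("TNT parse error: no xread block found")
  body <- sub(".*?xread", "", txt, ignore.case = TRUE)
  body <- sub(";.*", "", body)
  # normalize "/" separators (compact test dialect) to whitespace
  body <- gsub("/", " ", body, fixed = TRUE)
  toks <- .tokenize_tnt(body)
  if (length(toks) < 2L) stop("TNT parse error: missing dimensions")
  nchar <- suppressWarnings(as.integer(toks[1L]))
  ntax <- suppressWarnings(as.integer(toks[2L]))
  if (is.na(nchar) || is.na(ntax))
    stop("TNT parse error: dimensions must be integers, got '",
         toks[1L], " ", toks[2L], "'")
  toks <- toks[-(1:2)]
  taxa <- character(ntax)
  cells <- matrix(vector("list", ntax * nchar), nrow = ntax)
  pos <- 1L
  for (i in seq_len(ntax)) {
    if (pos > length(toks))
      stop("dimension error: expected ", ntax, " taxa, found ", i - 1L)
    taxa[i] <- toks[pos]; pos <- pos + 1L
    states <- character(0)
    # a row may be wrapped over several tokens; consume until nchar states
    while (length(states) < nchar && pos <= length(toks) &&
           grepl("^[-0-9?{([]", toks[pos])) {
      states <- c(states, .split_states(toks[pos]))
      pos <- pos + 1L
    }
    if (length(states) != nchar)
      stop("dimension error: taxon '", taxa[i], "' has ", length(states),
           " states, expected ", nchar)
    for (j in seq_len(nchar))
      cells[[i, j]] <- strsplit(states[j], "", fixed = TRUE)[[1L]]
  }
  rownames(cells) <- taxa
  morph_matrix(cells, taxa = taxa)
}

.tokenize_tnt <- function(body) {
  toks <- strsplit(body, "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

# split a row string like "01{02}?3" into per-cell state strings
.split_states <- function(row) {
  out <- character(0)
  i <- 1L
  chars <- strsplit(row, "", fixed = TRUE)[[1L]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("{", "[", "(")) {
      close <- c("{" = "}", "[" = "]", "(" = ")")[ch]
      j <- i + 1L
      grp <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        grp <- c(grp, chars[j]); j <- j + 1L
      }
      if (j > length(chars))
        stop("parse error: unclosed '", ch, "' in matrix row")
      out <- c(out, paste(grp, collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Write a morphological character matrix
#'
#' Writes NEXUS (`DATA` block, `DATATYPE=STANDARD`) or TNT `xread`
#' text.  Cells with more than one state are emitted in braces
#' (`{01}`); full-ambiguity cells are emitted as `?`.  Reading the
#' output back yields a matrix identical cell-for-cell.
#'
#' @param m a [morph_matrix].
#' @param file path, or `NULL` to return the text invisibly.
#' @param dialect `"nexus"` or `"tnt"`.
#' @return the text lines, invisibly.
#' @export
write_matrix <- function(m, file = NULL, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  rows <- .format_rows(m)
  lines <- if (dialect == "nexus") {
    symbols <- sort(unique(unlist(m$alphabets)))
    c("#NEXUS",
      "BEGIN DATA;",
      sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(m), n_char(m)),
      sprintf("FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
              paste(symbols, collapse = "")),
      "MATRIX",
      sprintf("%s  %s", format(m$taxa), rows),
      ";",
      "END;")
  } else {
    c("xread", sprintf("%d %d", n_char(m), n_taxa(m)),
      sprintf("%s  %s", format(m$taxa), rows),
      ";")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

.format_rows <- function(m) {
  cells <- matrix_cells(m)
  miss <- .missing_cells(m)
  nstate <- lengths(m$alphabets)
  vapply(seq_len(n_taxa(m)), function(i) {
    paste(vapply(seq_len(n_char(m)), function(j) {
      # a one-state character's only cell value is its symbol, not '?'
      if (miss[i, j] && nstate[j] > 1L) return("?")
      s <- cells[[i, j]]
      if (length(s) == 1L) s else paste0("{", paste(s, collapse = ""), "}")
    }, character(1)), collapse = "")
  }, character(1))
}

#' Read and write Newick trees
#'
#' Thin validated wrappers around ape's Newick support.  Reading
#' checks parenthesis balance and duplicate tip labels; tip labels are
#' normalized with [normalize_labels()].
#'
#' @param file path to a Newick file, or the Newick string itself when
#'   `text` is given.
#' @param text optional literal Newick string.
#' @return `read_tree`: a single `phylo` or a `multiPhylo` when the
#'   source holds several trees.
#' @export
read_tree <- function(file, text = NULL) {
  src <- if (!is.null(text)) text else paste(readLines(file, warn = FALSE),
                                             collapse = "\n")
  trees <- tryCatch(ape::read.tree(text = src),
                    error = function(e) stop("Newick parse error: ",
                                             conditionMessage(e),
                                             call. = FALSE))
  if (is.null(trees)) stop("Newick parse error: no tree in input")
  fix <- function(tr) {
    tr$tip.label <- normalize_labels(tr$tip.label)
    if (anyDuplicated(tr$tip.label))
      stop("duplicate tip label: ",
           tr$tip.label[duplicated(tr$tip.label)][1L], call. = FALSE)
    tr
  }
  if (inherits(trees, "multiPhylo")) {
    out <- lapply(trees, fix)
    class(out) <- "multiPhylo"
    if (length(out) == 1L) out[[1L]] else out
  } else fix(trees)
}

#' @rdname read_tree
#' @param tree a `phylo` or `multiPhylo`.
#' @export
write_tree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Read a stratigraphic range table
#'
#' Expects tab-separated columns `taxon`, `fad_ma`, `lad_ma` (first and
#' last appearance ages in Ma, `fad_ma >= lad_ma >= 0`).
#'
#' @param file path to the TSV file.
#' @return a validated data frame (see [strat_ranges()]).
#' @export
read_ranges <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("taxon", "fad_ma", "lad_ma")
  if (!all(need %in% names(df)))
    stop("range table must have columns: ", paste(need, collapse = ", "))
  strat_ranges(df$taxon, df$fad_ma, df$lad_ma)
}
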