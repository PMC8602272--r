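#' Discrete character-taxon matrices
#'
#' A `clado_matrix` holds a cladistic (discrete-character) matrix: for every
#' taxon and character either a non-empty set of integer states (singleton or
#' polymorphic), a missing entry (`?`), or an inapplicable entry (`-`).
#' Characters carry an ordering flag (`"ordered"` uses linear step costs,
#' `"unordered"` Fitch-style 0/1 costs) and a non-negative weight.
#'
#' Internally cells are stored as an integer matrix of state-set bitmasks
#' (state `s` present iff bit `s` is set; states 0--30), with `-1` for
#' missing and `-2` for inapplicable. Use [cm_cell()] / [cm_cells()] to
#' work with decoded state sets.
#'
#' @param cells a list-matrix (taxa in rows) whose elements are integer
#'   vectors of states, the string `"?"` (missing) or `"-"` (inapplicable).
#' @param taxa character vector of unique taxon names (row names of `cells`
#'   are used when omitted).
#' @param ordering character vector, one of `"ordered"`/`"unordered"` per
#'   character; a single value is recycled. Default `"unordered"`.
#' @param weights non-negative numeric vector per character; a single value
#'   is recycled. Default 1 (equal weighting).
#' @return an object of class `clado_matrix` with fields `taxa`, `codes`,
#'   `ordering`, `weights`.
#' @examples
#' cells <- matrix(list(0L, 1L, "?", 0L, c(0L, 1L), "-"), nrow = 2,
#'                 byrow = TRUE, dimnames = list(c("A", "B"), NULL))
#' m <- clado_matrix(cells)
#' cm_cell(m, "B", 2)  # polymorphic {0,1}
#' @export
clado_matrix <- function(cells, taxa = rownames(cells),
                         ordering = "unordered", weights = 1) {
  stopifnot(is.matrix(cells), is.list(cells))
  n <- nrow(cells); m <- ncol(cells)
  if (is.null(taxa)) stop("taxon names required (rownames or `taxa`)")
  codes <- matrix(vapply(cells, encode_cell, integer(1)), n, m)
  new_clado_matrix(codes, as.character(taxa), ordering, weights)
}

# low-level constructor on the bitmask representation
new_clado_matrix <- function(codes, taxa, ordering = "unordered",
                             weights = 1) {
  n <- nrow(codes); m <- ncol(codes)
  if (length(taxa) != n) stop("length(taxa) != nrow(codes)")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon name(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  ordering <- rep_len(as.character(ordering), m)
  if (!all(ordering %in% c("ordered", "unordered"))) {
    stop("ordering must be 'ordered' or 'unordered'")
  }
  weights <- rep_len(as.numeric(weights), m)
  if (any(is.na(weights)) || any(weights < 0)) {
    stop("character weights must be non-negative")
  }
  bad <- which(codes == 0L | is.na(codes))
  if (length(bad)) stop("empty or invalid state set at cell index ", bad[1])
  dimnames(codes) <- list(taxa, NULL)
  structure(list(taxa = taxa, codes = codes, ordering = ordering,
                 weights = weights),
            class = "clado_matrix")
}

CM_MISSING <- -1L
CM_INAPPLICABLE <- -2L

encode_cell <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (x == "?") return(CM_MISSING)
    if (x == "-") return(CM_INAPPLICABLE)
    stop("cell strings must be '?' or '-', got '", x, "'")
  }
  s <- unique(as.integer(x))
  if (!length(s) || any(is.na(s)) || any(s < 0L) || any(s > 30L)) {
    stop("states must be integers in 0..30")
  }
  sum(bitwShiftL(1L, s))
}

decode_code <- function(code) {
  if (code == CM_MISSING) return("?")
  if (code == CM_INAPPLICABLE) return("-")
  which(bitwAnd(code, bitwShiftL(1L, 0:30)) != 0L) - 1L
}

#' @describeIn clado_matrix decoded state set of one cell: an integer vector,
#'   or `"?"` / `"-"` for missing / inapplicable.
#' @param x a `clado_matrix`.
#' @param taxon taxon name or row index.
#' @param character character (column) index.
#' @export
cm_cell <- function(x, taxon, character) {
  decode_code(x$codes[taxon, character])
}

#' @describeIn clado_matrix all cells as a list-matrix of decoded state sets.
#' @export
cm_cells <- function(x) {
  out <- matrix(lapply(x$codes, decode_code), nrow(x$codes), ncol(x$codes))
  dimnames(out) <- list(x$taxa, NULL)
  out
}

#' @describeIn clado_matrix number of characters.
#' @export
cm_n_characters <- function(x) ncol(x$codes)

#' @describeIn clado_matrix logical matrix: TRUE where the cell is a scored
#'   state set (neither missing nor inapplicable).
#' @export
cm_is_scored <- function(x) x$codes > 0L

#' @describeIn clado_matrix per-taxon proportion of cells that are missing
#'   or inapplicable.
#' @export
cm_missing_fraction <- function(x) {
  rowMeans(x$codes < 0L)
}

#' @export
print.clado_matrix <- function(x, ...) {
  cat("<clado_matrix> ", length(x$taxa), " taxa x ", ncol(x$codes),
      " characters\n", sep = "")
  cat("  ordered characters: ", sum(x$ordering == "ordered"),
      "; mean missing/inapplicable: ",
      sprintf("%.1f%%", 100 * mean(x$codes < 0L)), "\n", sep = "")
  invisible(x)
}

# smallest and largest state of each scored cell; NA for ?/- cells.
# Used by the distance and parsimony code.
cm_state_bounds <- function(x) {
  codes <- x$codes
  lo <- hi <- matrix(NA_integer_, nrow(codes), ncol(codes),
                     dimnames = dimnames(codes))
  scored <- codes > 0L
  if (any(scored)) {
    vals <- codes[scored]
    lo[scored] <- vapply(vals, function(cd) min(decode_code(cd)), integer(1))
    hi[scored] <- vapply(vals, function(cd) max(decode_code(cd)), integer(1))
  }
  list(lo = lo, hi = hi)
}

#' Select taxa or characters from a clado_matrix
#'
#' @param x a `clado_matrix`.
#' @param taxa taxon names or indices to keep (default all).
#' @param characters character indices to keep (default all).
#' @return a `clado_matrix` restricted to the selection; ordering flags and
#'   weights follow the retained characters.
#' @export
cm_subset <- function(x, taxa = x$taxa, characters = seq_len(ncol(x$codes))) {
  codes <- x$codes[taxa, characters, drop = FALSE]
  new_clado_matrix(codes, rownames(codes), x$ordering[characters],
                   x$weights[characters])
}
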