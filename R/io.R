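#' Read a cladistic character matrix from NEXUS or TNT text
#'
#' Parses a discrete character-taxon matrix. Polymorphic cells may be written
#' `(01)`, `{01}` or `[01]` in either dialect; `?` is missing and `-`
#' inapplicable. Character ordering is read from a NEXUS `ASSUMPTIONS`
#' `TYPESET` line (`ord:` / `unord:` index lists) or a TNT `ccode` line
#' (`+` additive, `-` non-additive), defaulting to unordered; weights from a
#' NEXUS `WTSET` or TNT `ccode /w`. State symbols `0`-`9` then `A`-`U` map to
#' states 0--30. TNT `ccode` indices are 0-based, NEXUS sets 1-based.
#'
#' @param path path to the matrix file.
#' @param dialect `"nexus"`, `"tnt"`, or `"auto"` (sniff `#NEXUS` vs `xread`).
#' @return a [clado_matrix()].
#' @seealso [write_character_matrix()]
#' @export
read_character_matrix <- function(path, dialect = c("auto", "nexus", "tnt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    head_txt <- paste(lines[seq_len(min(10, length(lines)))], collapse = "\n")
    dialect <- if (grepl("#NEXUS", head_txt, ignore.case = TRUE)) "nexus"
               else if (grepl("\\bxread\\b", head_txt, ignore.case = TRUE)) "tnt"
               else stop("cannot detect dialect (no '#NEXUS' or 'xread' header)")
  }
  if (dialect == "nexus") parse_nexus_matrix(lines) else parse_tnt_matrix(lines)
}

STATE_SYMBOLS <- c(0:9, LETTERS[1:21])  # symbol index i -> state i-1

symbol_to_state <- function(ch, pos = "") {
  i <- match(toupper(ch), as.character(STATE_SYMBOLS))
  if (is.na(i)) stop("unknown state symbol '", ch, "'", pos)
  i - 1L
}

# tokenize one row of states: singles plus (..) {..} [..] groups
parse_state_row <- function(s, taxon) {
  s <- gsub("\\s+", "", s)
  chars <- strsplit(s, "")[[1]]
  codes <- integer(0); i <- 1L; n <- length(chars)
  closers <- c("(" = ")", "{" = "}", "[" = "]")
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% names(closers)) {
      j <- i + 1L; grp <- integer(0)
      while (j <= n && chars[j] != closers[[ch]]) {
        grp <- c(grp, symbol_to_state(chars[j],
                 sprintf(" (taxon %s, position %d)", taxon, j)))
        j <- j + 1L
      }
      if (j > n) stop("unclosed polymorphism group for taxon ", taxon)
      if (!length(grp)) stop("empty polymorphism group for taxon ", taxon)
      codes <- c(codes, sum(bitwShiftL(1L, unique(grp))))
      i <- j + 1L
    } else if (ch == "?") { codes <- c(codes, CM_MISSING); i <- i + 1L
    } else if (ch == "-") { codes <- c(codes, CM_INAPPLICABLE); i <- i + 1L
    } else {
      st <- symbol_to_state(ch, sprintf(" (taxon %s, position %d)", taxon, i))
      codes <- c(codes, bitwShiftL(1L, st)); i <- i + 1L
    }
  }
  codes
}

#' @keywords internal
normalize_taxon_name <- function(x) {
  x <- gsub("^['\"]|['\"]$", "", trimws(x))
  gsub("[ _]+", "_", x)
}

# expand "1-5" / "3" tokens (1-based) or "0.5" TNT ranges (0-based)
expand_index_tokens <- function(tokens, zero_based = FALSE, sep = "-") {
  out <- integer(0)
  for (tk in tokens) {
    tk <- trimws(tk)
    if (!nzchar(tk)) next
    if (grepl(sep, tk, fixed = TRUE)) {
      ab <- as.integer(strsplit(tk, sep, fixed = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else out <- c(out, as.integer(tk))
  }
  if (zero_based) out + 1L else out
}

parse_nexus_matrix <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  # strip NEXUS comments [...] except polymorphism groups inside MATRIX rows:
  # comments start "[" followed by non-digit; state groups contain symbols only
  txt <- gsub("\\[[^]]*[^]0-9A-Za-z{}() \t\n][^]]*\\]", "", txt)
  mm <- regmatches(txt, regexpr("(?is)MATRIX\\s*\n.*?;", txt, perl = TRUE))
  if (!length(mm)) stop("no MATRIX block found")
  rows <- strsplit(sub(";\\s*$", "", sub("(?is)^MATRIX\\s*\n", "", mm, perl = TRUE)),
                   "\n")[[1]]
  rows <- trimws(rows); rows <- rows[nzchar(rows)]
  taxa <- character(0); codes_list <- list()
  for (r in rows) {
    m <- regmatches(r, regexec("^('[^']+'|\"[^\"]+\"|\\S+)\\s+(\\S.*)$", r))[[1]]
    if (length(m) < 3) stop("cannot parse matrix row: ", r)
    nm <- normalize_taxon_name(m[2])
    if (nm %in% taxa) stop("duplicate taxon '", nm, "'")
    taxa <- c(taxa, nm)
    codes_list[[nm]] <- parse_state_row(m[3], nm)
  }
  nch <- unique(lengths(codes_list))
  if (length(nch) != 1) {
    bad <- names(codes_list)[lengths(codes_list) != max(table(lengths(codes_list)))]
    stop("ragged matrix: taxon row length differs for ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  codes <- do.call(rbind, codes_list)
  ordering <- rep("unordered", nch)
  weights <- rep(1, nch)
  # ASSUMPTIONS: TYPESET * name = ord: 1 3-5, unord: 2;
  ts <- regmatches(txt, regexpr("(?i)TYPESET[^;=]*=[^;]*;", txt, perl = TRUE))
  if (length(ts)) {
    body <- sub(";$", "", sub("^[^=]*=", "", ts))
    for (grp in strsplit(body, ",")[[1]]) {
      kv <- strsplit(grp, ":")[[1]]
      if (length(kv) != 2) next
      type <- tolower(trimws(kv[1]))
      idx <- expand_index_tokens(strsplit(trimws(kv[2]), "\\s+")[[1]])
      if (type %in% c("ord", "ordered")) ordering[idx] <- "ordered"
      if (type %in% c("unord", "unordered")) ordering[idx] <- "unordered"
    }
  }
  ws <- regmatches(txt, regexpr("(?i)WTSET[^;=]*=[^;]*;", txt, perl = TRUE))
  if (length(ws)) {
    body <- sub(";$", "", sub("^[^=]*=", "", ws))
    for (grp in strsplit(body, ",")[[1]]) {
      kv <- strsplit(grp, ":")[[1]]
      if (length(kv) != 2) next
      w <- as.numeric(trimws(kv[1]))
      idx <- expand_index_tokens(strsplit(trimws(kv[2]), "\\s+")[[1]])
      weights[idx] <- w
    }
  }
  new_clado_matrix(codes, taxa, ordering, weights)
}

parse_tnt_matrix <- function(lines) {
  lines <- sub("'.*?'", "", lines)  # strip quoted titles
  txt <- paste(lines, collapse = "\n")
  i0 <- regexpr("(?i)\\bxread\\b", txt, perl = TRUE)
  if (i0 < 0) stop("no xread block found")
  rest <- substring(txt, i0 + attr(i0, "match.length"))
  dims <- regmatches(rest, regexec("^\\s*(\\d+)\\s+(\\d+)", rest))[[1]]
  if (length(dims) < 3) stop("xread dimensions (nchar ntax) not found")
  nch <- as.integer(dims[2]); ntax <- as.integer(dims[3])
  body <- sub("^\\s*\\d+\\s+\\d+", "", rest)
  body <- strsplit(sub("(?s);.*$", ";", body, perl = TRUE), "\n")[[1]]
  body <- trimws(body)
  body <- body[nzchar(body) & body != ";"]
  taxa <- character(0); codes_list <- list()
  for (r in body) {
    if (startsWith(r, ";")) break
    m <- regmatches(r, regexec("^(\\S+)\\s+(\\S.*)$", r))[[1]]
    if (length(m) < 3) stop("cannot parse xread row: ", r)
    nm <- normalize_taxon_name(m[2])
    if (nm %in% taxa) stop("duplicate taxon '", nm, "'")
    taxa <- c(taxa, nm)
    codes_list[[nm]] <- parse_state_row(m[3], nm)
  }
  if (length(taxa) != ntax) {
    stop("xread declared ", ntax, " taxa but ", length(taxa), " rows found")
  }
  if (any(lengths(codes_list) != nch)) {
    bad <- names(codes_list)[lengths(codes_list) != nch]
    stop("ragged matrix: wrong row length for ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  codes <- do.call(rbind, codes_list)
  ordering <- rep("unordered", nch)
  weights <- rep(1, nch)
  # ccode + 0 2.4 - 1 /2 3 ;  (0-based indices; a.b = range)
  for (cc in regmatches(txt, gregexpr("(?i)ccode[^;]*;", txt, perl = TRUE))[[1]]) {
    toks <- strsplit(trimws(gsub(";", "", sub("(?i)ccode", "", cc, perl = TRUE))),
                     "\\s+")[[1]]
    mode <- NULL; wval <- NULL
    for (tk in toks) {
      if (tk == "+") { mode <- "ordered"; wval <- NULL }
      else if (tk == "-") { mode <- "unordered"; wval <- NULL }
      else if (startsWith(tk, "/")) { wval <- as.numeric(substring(tk, 2)); mode <- NULL }
      else if (tk %in% c("[", "]", "(", ")", "*", "=")) next
      else {
        idx <- expand_index_tokens(tk, zero_based = TRUE, sep = ".")
        if (!is.null(mode)) ordering[idx] <- mode
        if (!is.null(wval)) weights[idx] <- wval
      }
    }
  }
  new_clado_matrix(codes, taxa, ordering, weights)
}

#' Write a character matrix to NEXUS or TNT text
#'
#' Writes single states, polymorphisms as `(..)`, missing `?` and
#' inapplicable `-`; ordering as a NEXUS `ASSUMPTIONS` `TYPESET` (or TNT
#' `ccode +`) and non-unit weights as a `WTSET` (or `ccode /w`). The NEXUS
#' writer and [read_character_matrix()] round-trip exactly.
#'
#' @param x a [clado_matrix()].
#' @param path output file path.
#' @param dialect `"nexus"` (default) or `"tnt"`.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(x, path, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  fmt_cell <- function(code) {
    s <- decode_code(code)
    if (is.character(s)) return(s)
    sym <- as.character(STATE_SYMBOLS)[s + 1L]
    if (length(sym) == 1L) sym else paste0("(", paste(sym, collapse = ""), ")")
  }
  rows <- apply(x$codes, 1, function(r) paste(vapply(r, fmt_cell, ""), collapse = ""))
  nm <- format(x$taxa, width = max(nchar(x$taxa)))
  ord_idx <- which(x$ordering == "ordered")
  if (dialect == "nexus") {
    out <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(x$taxa),
                     ncol(x$codes)),
             "FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789ABCDEFGHIJKLMNOPQRSTU\" MISSING=? GAP=-;",
             "MATRIX", paste(nm, rows), ";", "END;")
    assum <- character(0)
    if (length(ord_idx)) {
      assum <- c(assum, sprintf("TYPESET * UNTITLED = ord: %s;",
                                paste(ord_idx, collapse = " ")))
    }
    wdiff <- which(x$weights != 1)
    if (length(wdiff)) {
      per_w <- split(wdiff, x$weights[wdiff])
      assum <- c(assum, sprintf("WTSET * UNTITLED = %s;",
        paste(vapply(names(per_w), function(w)
          paste0(w, ": ", paste(per_w[[w]], collapse = " ")), ""),
          collapse = ", ")))
    }
    if (length(assum)) out <- c(out, "BEGIN ASSUMPTIONS;", assum, "END;")
  } else {
    out <- c("xread", sprintf("%d %d", ncol(x$codes), length(x$taxa)),
             paste(nm, rows), ";")
    if (length(ord_idx)) {
      out <- c(out, sprintf("ccode + %s;",
                            paste(ord_idx - 1L, collapse = " ")))
    }
    wdiff <- which(x$weights != 1)
    for (w in unique(x$weights[wdiff])) {
      out <- c(out, sprintf("ccode /%g %s;",
                            w, paste(which(x$weights == w) - 1L, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read trees from a Newick or NEXUS file
#'
#' One Newick string per line, or a NEXUS `TREES` block. Tip labels are
#' normalized (quotes stripped, whitespace/underscore runs collapsed to a
#' single underscore) so they match matrix taxon names.
#'
#' @param path tree file.
#' @param matrix_taxa optional character vector; tips absent from it trigger
#'   a warning listing them.
#' @return a list of `phylo` objects (class `multiPhylo`).
#' @export
read_tree_file <- function(path, matrix_taxa = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_nexus <- any(grepl("#NEXUS", utils::head(lines, 3), ignore.case = TRUE))
  if (!is_nexus) {
    for (ln in lines[nzchar(trimws(lines))]) {
      depth <- 0L
      for (i in seq_len(nchar(ln))) {
        ch <- substr(ln, i, i)
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") depth <- depth - 1L
        if (depth < 0L) stop("unmatched ')' at character offset ", i)
      }
      if (depth > 0L) stop("unmatched '(' (", depth,
                           " unclosed) in line: ", substr(ln, 1, 40))
    }
  }
  trees <- if (is_nexus) ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)  # -> multiPhylo
  trees <- lapply(trees, function(tr) {
    tr$tip.label <- normalize_taxon_name(tr$tip.label)
    tr
  })
  class(trees) <- "multiPhylo"
  if (!is.null(matrix_taxa)) {
    matrix_taxa <- normalize_taxon_name(matrix_taxa)
    missing <- unique(unlist(lapply(trees, function(tr)
      setdiff(tr$tip.label, matrix_taxa))))
    if (length(missing)) {
      warning("tip label(s) absent from matrix: ",
              paste(missing, collapse = ", "))
    }
  }
  trees
}

#' Stage-level time-bin table
#'
#' An ordered set of contiguous time bins, each `(label, older bound,
#' younger bound)` in Ma. Ages are assigned to bins half-open on the young
#' side: an age `a` falls in the bin with `older >= a > younger`.
#'
#' @param labels bin labels, oldest first.
#' @param older,younger numeric bounds in Ma, strictly decreasing;
#'   `older[i+1]` must equal `younger[i]` (contiguity).
#' @return a `data.frame` of class `bin_table`.
#' @export
bin_table <- function(labels, older, younger) {
  stopifnot(length(labels) == length(older), length(older) == length(younger))
  if (any(older <= younger)) stop("each bin needs older > younger bound")
  if (length(labels) > 1 &&
      !isTRUE(all.equal(older[-1], younger[-length(younger)]))) {
    stop("bins must be contiguous and in decreasing age order")
  }
  if (anyDuplicated(labels)) stop("duplicate bin labels")
  structure(data.frame(label = labels, older = older, younger = younger,
                       stringsAsFactors = FALSE),
            class = c("bin_table", "data.frame"))
}

#' @describeIn bin_table the four Carnian--Middle Jurassic stage-level bins
#'   used throughout the package examples (233.2, 225.7, 201.3, 182.7,
#'   163.5 Ma boundaries).
#' @export
default_bin_table <- function() {
  bin_table(c("Carnian", "Norian-Rhaetian", "pre-Toarcian", "Toarcian-MJ"),
            older = c(233.2, 225.7, 201.3, 182.7),
            younger = c(225.7, 201.3, 182.7, 163.5))
}

#' @describeIn bin_table all bins overlapped by the age interval
#'   `[lad, fad]`; a point age returns one bin.
#' @param bins a `bin_table`.
#' @param fad,lad first/last appearance ages in Ma (`fad >= lad`).
#' @export
bins_for_range <- function(bins, fad, lad = fad) {
  stopifnot(inherits(bins, "bin_table"))
  if (any(fad < lad)) stop("fad must be >= lad")
  hit <- fad > bins$younger & lad <= bins$older
  bins$label[hit]
}

#' Read a taxon metadata table
#'
#' Reads a CSV/TSV with columns `taxon`, `fad_ma`, `lad_ma` (optional,
#' defaults to `fad_ma`), `bins` (optional, `;`-separated labels),
#' `locomotion` (`biped`/`quadruped`; blank or NA becomes `unknown`),
#' `continent`, `log_body_mass`, and optional `femoral_length`,
#' `humeral_circ`, `femoral_circ`. When `bins` is absent or empty the taxon
#' is assigned every bin its `[lad, fad]` range overlaps.
#'
#' @param path delimited file (separator sniffed from the header line).
#' @param bins a [bin_table()]; defaults to [default_bin_table()].
#' @return a `data.frame` with a list-column `bins`; the bin table is
#'   attached as attribute `"bin_table"`.
#' @export
read_taxon_metadata <- function(path, bins = default_bin_table()) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", na.strings = c("NA", ""))
  if (!all(c("taxon", "fad_ma") %in% names(df))) {
    stop("metadata needs at least 'taxon' and 'fad_ma' columns")
  }
  df$taxon <- normalize_taxon_name(df$taxon)
  if (anyDuplicated(df$taxon)) stop("duplicate taxon in metadata")
  if (is.null(df$lad_ma)) df$lad_ma <- df$fad_ma
  df$lad_ma <- ifelse(is.na(df$lad_ma), df$fad_ma, df$lad_ma)
  bad <- which(df$fad_ma < df$lad_ma)
  if (length(bad)) stop("fad_ma < lad_ma for taxon ", df$taxon[bad[1]])
  if (any(df$lad_ma <= 0)) stop("ages must be positive (Ma)")
  given <- if (is.null(df$bins)) rep(NA_character_, nrow(df)) else df$bins
  df$bins <- lapply(seq_len(nrow(df)), function(i) {
    if (!is.na(given[i]) && nzchar(trimws(given[i]))) {
      labs <- trimws(strsplit(given[i], ";")[[1]])
      unknown <- setdiff(labs, bins$label)
      if (length(unknown)) stop("unknown bin label: ",
                                paste(unknown, collapse = ", "))
      labs
    } else bins_for_range(bins, df$fad_ma[i], df$lad_ma[i])
  })
  if (is.null(df$locomotion)) df$locomotion <- NA_character_
  df$locomotion <- ifelse(is.na(df$locomotion) | !nzchar(trimws(df$locomotion)),
                          "unknown", trimws(df$locomotion))
  ok <- df$locomotion %in% c("biped", "quadruped", "unknown")
  if (!all(ok)) stop("locomotion must be biped/quadruped/unknown, got: ",
                     df$locomotion[!ok][1])
  attr(df, "bin_table") <- bins
  df
}

fmt7 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 7), format = "fg", digits = 7))
}

#' Write pipeline result tables
#'
#' Writes the disparity table (`Bin | metric | value | lower | upper`, TSV,
#' 7 significant digits), ordination coordinates (`taxon, PCo1..PCok`, CSV),
#' an optional regression table (TSV) and an optional plain-text log.
#'
#' @param disparity data.frame with columns `bin`, `metric`, `value`,
#'   `lower`, `upper` (extra columns are kept).
#' @param dir output directory (created if needed).
#' @param coordinates optional numeric matrix, taxa in rownames.
#' @param regressions optional data.frame.
#' @param log_lines optional character vector written to `pipeline.log`.
#' @return named character vector of the files written, invisibly.
#' @export
write_results <- function(disparity, dir, coordinates = NULL,
                          regressions = NULL, log_lines = NULL) {
  if (is.null(disparity) || !nrow(disparity)) stop("no results to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  d <- disparity
  for (cl in intersect(c("value", "lower", "upper"), names(d))) {
    d[[cl]] <- fmt7(d[[cl]])
  }
  names(d)[names(d) == "bin"] <- "Bin"
  f <- file.path(dir, "disparity.tsv")
  utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["disparity"] <- f
  if (!is.null(coordinates)) {
    cd <- data.frame(taxon = rownames(coordinates),
                     signif(coordinates, 7), check.names = FALSE)
    names(cd)[-1] <- paste0("PCo", seq_len(ncol(coordinates)))
    f <- file.path(dir, "coordinates.csv")
    utils::write.csv(cd, f, row.names = FALSE, quote = FALSE)
    files["coordinates"] <- f
  }
  if (!is.null(regressions)) {
    r <- regressions
    num <- vapply(r, is.numeric, TRUE)
    r[num] <- lapply(r[num], fmt7)
    f <- file.path(dir, "regressions.tsv")
    utils::write.table(r, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["regressions"] <- f
  }
  if (!is.null(log_lines)) {
    f <- file.path(dir, "pipeline.log")
    writeLines(log_lines, f)
    files["log"] <- f
  }
  invisible(files)
}
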