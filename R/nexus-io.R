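# NEXUS DATA/CHARACTERS block I/O for discrete matrices.  A purpose-built
# parser is used (rather than ape's read.nexus.data) because the package
# contract needs the FORMAT symbol declarations, MIXED datatypes, CHARSET
# partitions and the MISSING/GAP cell distinction, none of which survive the
# available readers.  Dialect coverage: DIMENSIONS, FORMAT (DATATYPE incl.
# MIXED(...), MISSING, GAP, SYMBOLS, INTERLEAVE), MATRIX (sequential or
# interleaved, quoted taxon labels), and CHARSET commands in SETS /
# ASSUMPTIONS blocks.  Polymorphic cells "(01)"/"{01}" are read as MISSING.

DNA_ALPHABET <- c("A", "C", "G", "T")

.strip_nexus_comments <- function(text) {
  # remove bracketed comments, tolerating one level of nesting
  repeat {
    out <- gsub("\\[[^\\[\\]]*\\]", "", text)
    if (identical(out, text)) return(out)
    text <- out
  }
}

.parse_id_ranges <- function(spec, nchar_total) {
  # "1-54 60 62-." -> integer vector
  toks <- strsplit(trimws(spec), "\\s+")[[1]]
  out <- integer(0)
  for (tk in toks) {
    if (grepl("-", tk, fixed = TRUE)) {
      ab <- strsplit(tk, "-", fixed = TRUE)[[1]]
      a <- as.integer(ab[1])
      b <- if (ab[2] == ".") nchar_total else as.integer(ab[2])
      out <- c(out, seq.int(a, b))
    } else if (tk == ".") out <- c(out, nchar_total)
    else out <- c(out, as.integer(tk))
  }
  out
}

#' Read a character matrix from a NEXUS file
#'
#' Parses the first DATA or CHARACTERS block.  The FORMAT MISSING symbol
#' (default `?`) becomes MISSING, the GAP symbol (default `-`) becomes
#' INAPPLICABLE.  `DATATYPE=MIXED(STANDARD:...,DNA:...)` and CHARSET
#' commands, when present, set per-column partition tags; otherwise all
#' columns are tagged `"molecular"` (DNA/RNA datatypes) or `"morphology"`.
#' In DNA partitions, IUPAC ambiguity codes are recoded as MISSING.
#'
#' @param file path to a NEXUS file, or `NULL` if `text` is given.
#' @param text NEXUS document as a single string.
#' @return a [char_matrix].
#' @export
read_nexus_matrix <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop_domain("supply exactly one of `file` or `text`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  text <- .strip_nexus_comments(text)
  m <- regexpr("(?s)begin\\s+(data|characters)\\s*;.*?\\bend\\s*;", text,
               ignore.case = TRUE, perl = TRUE)
  if (m < 0) stop_domain("no DATA or CHARACTERS block found")
  block <- regmatches(text, m)

  grab <- function(pat) {
    mm <- regexpr(pat, block, ignore.case = TRUE, perl = TRUE)
    if (mm < 0) return(NULL)
    sub(pat, "\\1", regmatches(block, mm), ignore.case = TRUE, perl = TRUE)
  }
  ntax <- as.integer(grab("ntax\\s*=\\s*(\\d+)"))
  nchar_total <- as.integer(grab("nchar\\s*=\\s*(\\d+)"))
  if (!length(ntax) || !length(nchar_total))
    stop_domain("DIMENSIONS with NTAX and NCHAR required")
  datatype <- toupper(grab("datatype\\s*=\\s*(mixed\\s*\\([^)]*\\)|\\w+)") %||% "STANDARD")
  missing_sym <- grab("missing\\s*=\\s*(\\S)") %||% "?"
  gap_sym <- grab("gap\\s*=\\s*(\\S)") %||% "-"
  symbols_decl <- grab("symbols\\s*=\\s*\"([^\"]*)\"")
  interleaved <- grepl("interleave", block, ignore.case = TRUE)

  mm <- regexpr("(?s)\\bmatrix\\b(.*?);", block, ignore.case = TRUE,
                perl = TRUE)
  if (mm < 0) stop_domain("no MATRIX command in block")
  body <- sub("(?i)matrix", "", regmatches(block, mm), perl = TRUE)
  body <- sub(";\\s*$", "", body)
  lines <- trimws(strsplit(body, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]

  rows <- list(); order_seen <- character(0)
  for (ln in lines) {
    if (grepl("^'", ln)) {
      mm2 <- regexpr("^'((?:[^']|'')*)'", ln, perl = TRUE)
      taxon <- gsub("''", "'", sub("^'((?:[^']|'')*)'.*$", "\\1", ln, perl = TRUE))
      seqpart <- substring(ln, attr(mm2, "match.length") + 1L)
    } else {
      taxon <- sub("^(\\S+).*$", "\\1", ln)
      seqpart <- sub("^\\S+", "", ln)
    }
    cells <- .parse_cell_run(seqpart)
    if (!length(cells)) next
    if (is.null(rows[[taxon]])) {
      if (!interleaved && length(rows) && taxon %in% names(rows))
        stop_domain("duplicate taxon in matrix: ", taxon)
      rows[[taxon]] <- cells
      order_seen <- c(order_seen, taxon)
    } else {
      if (!interleaved) stop_domain("duplicate taxon in matrix: ", taxon)
      rows[[taxon]] <- c(rows[[taxon]], cells)
    }
  }
  if (length(rows) != ntax)
    stop_domain("matrix has ", length(rows), " taxa, DIMENSIONS declares ", ntax)
  lens <- vapply(rows, length, 1L)
  if (any(lens != nchar_total))
    stop_domain("ragged matrix: rows of length ",
                paste(unique(lens), collapse = "/"),
                " vs NCHAR=", nchar_total)
  cells <- do.call(rbind, rows[order_seen])
  rownames(cells) <- order_seen
  cells[cells == missing_sym] <- MISSING_CELL
  cells[cells == gap_sym] <- INAPP_CELL

  # per-column partition/datatype
  part <- rep("morphology", nchar_total)
  coltype <- rep("STANDARD", nchar_total)
  if (grepl("^MIXED", datatype)) {
    segs <- strsplit(sub("^MIXED\\s*\\(([^)]*)\\)$", "\\1", datatype), ",")[[1]]
    for (sg in segs) {
      kv <- strsplit(trimws(sg), ":")[[1]]
      ids <- .parse_id_ranges(kv[2], nchar_total)
      coltype[ids] <- toupper(trimws(kv[1]))
    }
  } else coltype[] <- datatype
  part[coltype %in% c("DNA", "RNA", "NUCLEOTIDE")] <- "molecular"

  # CHARSETs anywhere in the document override partition tags
  cs <- gregexpr("charset\\s+(\\S+)\\s*=\\s*([^;]+);", text,
                 ignore.case = TRUE, perl = TRUE)[[1]]
  if (cs[1] > 0) {
    for (i in seq_along(cs)) {
      frag <- substring(text, cs[i], cs[i] + attr(cs, "match.length")[i] - 1L)
      nm <- sub("charset\\s+(\\S+)\\s*=.*", "\\1", frag, ignore.case = TRUE)
      ids <- .parse_id_ranges(sub("charset\\s+\\S+\\s*=\\s*([^;]+);", "\\1",
                                  frag, ignore.case = TRUE), nchar_total)
      part[ids] <- nm
    }
  }

  # alphabets: DNA columns get ACGT (ambiguity -> MISSING); standard columns
  # get declared SYMBOLS, else observed symbols
  dna_cols <- coltype %in% c("DNA", "RNA", "NUCLEOTIDE")
  if (any(dna_cols)) {
    sub_cells <- toupper(cells[, dna_cols, drop = FALSE])
    sub_cells[sub_cells == "U"] <- "T"
    sub_cells[!(sub_cells %in% c(DNA_ALPHABET, MISSING_CELL, INAPP_CELL))] <-
      MISSING_CELL
    cells[, dna_cols] <- sub_cells
  }
  std_symbols <- if (!is.null(symbols_decl))
    strsplit(gsub("\\s+", "", symbols_decl), "")[[1]]
  else sort(setdiff(unique(as.vector(cells[, !dna_cols, drop = FALSE])),
                    c(MISSING_CELL, INAPP_CELL)))
  alphabets <- lapply(split(seq_len(nchar_total), part), function(j)
    if (all(dna_cols[j])) DNA_ALPHABET else std_symbols)

  char_matrix(cells, partition = part, alphabets = alphabets)
}

# split one run of matrix text into cells; "(..)" / "{..}" -> MISSING
.parse_cell_run <- function(s) {
  chars <- strsplit(gsub("[ \t]", "", s), "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      j <- i
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      out <- c(out, MISSING_CELL)
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Write a character matrix as NEXUS
#'
#' Emits one DATA block (DATATYPE=MIXED when both standard and DNA
#' partitions are present, per the MrBayes dialect) and a SETS block with
#' one CHARSET per partition tag, so [read_nexus_matrix] round-trips cells,
#' taxon order and partitions.
#'
#' @param x a [char_matrix].
#' @param file output path, or `NULL` to return the document as a string.
#' @return the NEXUS document, invisibly when written to `file`.
#' @export
write_nexus_matrix <- function(x, file = NULL) {
  stopifnot(inherits(x, "char_matrix"))
  is_dna <- vapply(x$partition, function(p)
    setequal(x$alphabets[[p]], DNA_ALPHABET), logical(1))
  std_syms <- sort(unique(unlist(x$alphabets[unique(x$partition[!is_dna])])))
  fmt <- if (any(is_dna) && any(!is_dna)) {
    seg <- function(type, idx) sprintf("%s:%s", type, .format_ranges(idx))
    sprintf("datatype=mixed(%s,%s)",
            seg("standard", which(!is_dna)), seg("dna", which(is_dna)))
  } else if (all(is_dna)) "datatype=dna" else "datatype=standard"
  if (any(!is_dna) && length(std_syms))
    fmt <- paste0(fmt, sprintf(" symbols=\"%s\"", paste(std_syms, collapse = " ")))
  fmt <- paste0(fmt, " missing=? gap=-")

  labw <- max(nchar(rownames(x$cells))) + 2L
  mat_lines <- vapply(seq_len(nrow(x$cells)), function(i) {
    lab <- rownames(x$cells)[i]
    if (grepl("\\s", lab)) lab <- paste0("'", lab, "'")
    sprintf("  %-*s %s", labw, lab, paste(x$cells[i, ], collapse = ""))
  }, character(1))

  sets <- vapply(unique(x$partition), function(p)
    sprintf("  charset %s = %s;", p, .format_ranges(which(x$partition == p))),
    character(1))

  doc <- c("#NEXUS", "",
           "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(x$cells), ncol(x$cells)),
           sprintf("  FORMAT %s;", fmt),
           "  MATRIX", mat_lines, "  ;", "END;", "",
           "BEGIN SETS;", sets, "END;")
  doc <- paste(doc, collapse = "\n")
  if (is.null(file)) return(doc)
  writeLines(doc, file)
  invisible(doc)
}

# compress sorted integer positions into "a-b c d-e"
.format_ranges <- function(idx) {
  idx <- sort(unique(idx))
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  paste(vapply(runs, function(r)
    if (length(r) == 1L) as.character(r) else paste0(r[1], "-", r[length(r)]),
    character(1)), collapse = " ")
}
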