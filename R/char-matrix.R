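# Discrete character matrices: taxa x columns of state symbols with MISSING
# ("?") and INAPPLICABLE ("-") cells, per-column partition tags, and 1-based
# column ids that stay stable across filtering (so character numbers cited
# in analyses remain addressable after columns are dropped).
#
# INAPPLICABLE is stored distinctly for round-tripping but is treated
# identically to MISSING by informativeness, parsimony and missing-data
# computations, matching the genus-level coding rule "missing if unknown or
# inapplicable".

MISSING_CELL <- "?"
INAPP_CELL <- "-"

#' Construct a character matrix
#'
#' @param cells character matrix, rows = taxa (rownames required), columns =
#'   characters; cells are state symbols, `"?"` (missing) or `"-"`
#'   (inapplicable).
#' @param partition character vector of per-column partition tags (recycled);
#'   default `"morphology"`.
#' @param col_id integer 1-based column ids; default `1:ncol`.
#' @param alphabets named list, partition tag -> allowed state symbols;
#'   inferred from the cells when omitted.
#' @return an object of class `char_matrix`.
#' @export
char_matrix <- function(cells, partition = "morphology", col_id = NULL,
                        alphabets = NULL) {
  stopifnot(is.matrix(cells), is.character(cells))
  if (is.null(rownames(cells)) || any(!nzchar(rownames(cells))))
    stop_domain("cells must have nonempty taxon rownames")
  if (anyDuplicated(rownames(cells)))
    stop_domain("duplicate taxon labels")
  partition <- rep_len(as.character(partition), ncol(cells))
  col_id <- if (is.null(col_id)) seq_len(ncol(cells)) else as.integer(col_id)
  if (length(col_id) != ncol(cells) || anyDuplicated(col_id))
    stop_domain("col_id must be unique and match the column count")
  if (is.null(alphabets)) {
    alphabets <- lapply(split(seq_len(ncol(cells)), partition), function(j) {
      v <- unique(as.vector(cells[, j, drop = FALSE]))
      sort(setdiff(v, c(MISSING_CELL, INAPP_CELL)))
    })
  }
  for (p in unique(partition)) {
    if (is.null(alphabets[[p]]))
      stop_domain("no alphabet declared for partition '", p, "'")
    bad <- setdiff(unique(as.vector(cells[, partition == p, drop = FALSE])),
                   c(alphabets[[p]], MISSING_CELL, INAPP_CELL))
    if (length(bad))
      stop_domain("undeclared symbols in partition '", p, "': ",
                  paste(bad, collapse = " "))
  }
  structure(list(cells = cells, partition = partition,
                 col_id = col_id, alphabets = alphabets),
            class = "char_matrix")
}

#' @export
dim.char_matrix <- function(x) dim(x$cells)

#' @export
print.char_matrix <- function(x, ...) {
  parts <- table(x$partition)
  cat("char_matrix:", nrow(x$cells), "taxa x", ncol(x$cells), "characters (",
      paste(sprintf("%s: %d", names(parts), parts), collapse = ", "), ")\n")
  invisible(x)
}

taxa_labels <- function(x) rownames(x$cells)

#' Subset a character matrix
#'
#' @param x a [char_matrix].
#' @param taxa taxon labels to keep (default all).
#' @param ids original 1-based column ids to keep (default all).
#' @return a [char_matrix]; column ids are preserved, not renumbered.
#' @export
subset_matrix <- function(x, taxa = NULL, ids = NULL) {
  stopifnot(inherits(x, "char_matrix"))
  ri <- if (is.null(taxa)) seq_len(nrow(x$cells)) else {
    miss <- setdiff(taxa, rownames(x$cells))
    if (length(miss)) stop_domain("unknown taxa: ", paste(miss, collapse = ", "))
    match(taxa, rownames(x$cells))
  }
  ci <- if (is.null(ids)) seq_len(ncol(x$cells)) else {
    miss <- setdiff(ids, x$col_id)
    if (length(miss)) stop_domain("unknown column ids: ", paste(miss, collapse = ", "))
    match(ids, x$col_id)
  }
  char_matrix(x$cells[ri, ci, drop = FALSE], x$partition[ci],
              x$col_id[ci], x$alphabets)
}

# effective state of a cell for computation: symbol, or NA if missing /
# inapplicable / outside the declared alphabet (e.g. IUPAC ambiguity)
.effective_states <- function(cells, alphabet) {
  out <- cells
  out[!(out %in% alphabet)] <- NA_character_
  out
}

# ---- informativeness ------------------------------------------------------

#' Is a character column parsimony informative?
#'
#' An unordered column is parsimony informative iff at least two distinct
#' states each occur in at least two taxa (then and only then does its
#' minimum tree length vary across topologies).  `"?"`, `"-"` and symbols
#' outside `alphabet` are excluded from the counts.
#'
#' @param column character vector of cells.
#' @param alphabet state symbols to count; default: everything except
#'   `"?"`/`"-"`.
#' @return logical.
#' @export
is_parsimony_informative <- function(column, alphabet = NULL) {
  if (is.null(alphabet))
    alphabet <- setdiff(unique(column), c(MISSING_CELL, INAPP_CELL))
  tab <- table(.effective_states(column, alphabet))
  sum(tab >= 2L) >= 2L
}

#' Keep only parsimony-informative columns
#'
#' @param x a [char_matrix].
#' @return list with `matrix` (the filtered [char_matrix], surviving columns
#'   keeping their original ids) and `dropped` (integer ids of removed
#'   columns).  Idempotent; re-filtering after taxon subsetting may drop
#'   further columns.
#' @export
filter_informative <- function(x) {
  stopifnot(inherits(x, "char_matrix"))
  keep <- vapply(seq_len(ncol(x$cells)), function(j)
    is_parsimony_informative(x$cells[, j], x$alphabets[[x$partition[j]]]),
    logical(1))
  list(matrix = subset_matrix(x, ids = x$col_id[keep]),
       dropped = x$col_id[!keep])
}

# ---- missing-data accounting ----------------------------------------------

#' Per-taxon, per-partition missing-data percentages
#'
#' @param x a [char_matrix].
#' @param treat_inapplicable_as_missing count `"-"` cells as missing
#'   (default TRUE, the coding rule used throughout this package).
#' @return data.frame with column `taxon` and one numeric column per
#'   partition: 100 * missing cells / partition columns (full precision;
#'   round to one decimal for report rendering).
#' @export
missing_percentages <- function(x, treat_inapplicable_as_missing = TRUE) {
  stopifnot(inherits(x, "char_matrix"))
  miss_symbols <- if (treat_inapplicable_as_missing)
    c(MISSING_CELL, INAPP_CELL) else MISSING_CELL
  parts <- unique(x$partition)
  out <- data.frame(taxon = rownames(x$cells), stringsAsFactors = FALSE)
  for (p in parts) {
    cols <- x$partition == p
    ismiss <- matrix(x$cells[, cols, drop = FALSE] %in% miss_symbols,
                     nrow = nrow(x$cells))
    out[[p]] <- 100 * rowSums(ismiss) / sum(cols)
  }
  out
}

# ---- weighting by replication ---------------------------------------------

#' Replicate every column k times
#'
#' Integer character weighting by repetition: each original column appears
#' `k` times contiguously, so a 54-column matrix with `k = 53` becomes a
#' 2862-column matrix.  Replicated columns get fresh sequential ids; the
#' originating id is recorded in attribute `"source_id"`.
#'
#' @param x a [char_matrix].
#' @param k positive integer.
#' @return a [char_matrix].
#' @export
replicate_columns <- function(x, k) {
  stopifnot(inherits(x, "char_matrix"))
  if (!is_scalar_number(k) || k < 1 || k != round(k))
    stop_domain("`k` must be a positive integer")
  k <- as.integer(k)
  idx <- rep(seq_len(ncol(x$cells)), each = k)
  out <- char_matrix(x$cells[, idx, drop = FALSE], x$partition[idx],
                     col_id = seq_along(idx), alphabets = x$alphabets)
  attr(out, "source_id") <- x$col_id[idx]
  out
}

# ---- genus -> species expansion -------------------------------------------

#' Expand genus-level rows to species-level rows
#'
#' Each genus row is copied verbatim to every species mapped to it (the
#' assumption that morphology does not vary within genera); genera absent
#' from the map keep their single row under their own label.
#'
#' @param x a [char_matrix] with genus-level rows.
#' @param species_map named list: genus label -> character vector of species
#'   labels.
#' @return a [char_matrix] with one row per species.
#' @export
expand_genus_to_species <- function(x, species_map) {
  stopifnot(inherits(x, "char_matrix"), is.list(species_map))
  genera <- names(species_map)
  missing_genus <- setdiff(genera, rownames(x$cells))
  if (length(missing_genus))
    stop_domain("species map to absent genera: ",
                paste(missing_genus, collapse = ", "))
  if (any(vapply(species_map, length, 1L) == 0L))
    stop_domain("empty species list for a genus")
  rows <- list()
  for (g in rownames(x$cells)) {
    sp <- if (g %in% genera) species_map[[g]] else g
    for (s in sp) rows[[s]] <- x$cells[g, ]
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- names(rows)
  char_matrix(cells, x$partition, x$col_id, x$alphabets)
}

# ---- partition combination ------------------------------------------------

#' Combine two character matrices into one partitioned matrix
#'
#' Rows are unioned by taxon label; taxa absent from one input get MISSING
#' for all of its columns (e.g. taxa with no molecular data).  Column ids of
#' the second matrix are renumbered to follow the first so ids stay unique.
#'
#' @param a,b [char_matrix] objects with distinct partition tags.
#' @return a [char_matrix].
#' @export
combine_partitions <- function(a, b) {
  stopifnot(inherits(a, "char_matrix"), inherits(b, "char_matrix"))
  shared_parts <- intersect(unique(a$partition), unique(b$partition))
  if (length(shared_parts))
    stop_domain("inputs share partition tags: ",
                paste(shared_parts, collapse = ", "))
  taxa <- union(rownames(a$cells), rownames(b$cells))
  fill <- function(x) {
    out <- matrix(MISSING_CELL, length(taxa), ncol(x$cells),
                  dimnames = list(taxa, NULL))
    out[rownames(x$cells), ] <- x$cells
    out
  }
  cells <- cbind(fill(a), fill(b))
  char_matrix(cells,
              partition = c(a$partition, b$partition),
              col_id = c(a$col_id, max(a$col_id) + seq_along(b$col_id)),
              alphabets = c(a$alphabets, b$alphabets))
}

#' Split a combined matrix back into per-partition matrices
#'
#' Rows that are entirely MISSING within a partition are dropped from that
#' partition's matrix (they were filler added by [combine_partitions]).
#'
#' @param x a [char_matrix].
#' @return named list of [char_matrix], one per partition tag.
#' @export
split_by_partition <- function(x) {
  stopifnot(inherits(x, "char_matrix"))
  out <- list()
  for (p in unique(x$partition)) {
    cols <- x$partition == p
    cells <- x$cells[, cols, drop = FALSE]
    present <- rowSums(cells != MISSING_CELL) > 0L
    out[[p]] <- char_matrix(cells[present, , drop = FALSE],
                            partition = p, col_id = seq_len(sum(cols)),
                            alphabets = x$alphabets[p])
  }
  out
}
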