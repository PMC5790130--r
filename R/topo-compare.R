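# Contradiction difference (CD): how much two summary topologies actively
# disagree, ignoring differences that are only a matter of resolution.
#
# After pruning both trees to their shared tips, a split of tree A counts as
# contradicted if at least one split of tree B segregates an overlapping but
# different, non-nested set of taxa.  With N_AB and N_BA the per-tree counts,
#
#   CD = (N_AB + N_BA) / (2 * (n_shared - 2))
#
# which lies in [0, 1]: a star tree contradicts nothing (CD 0 against any
# tree), and two fully conflicting resolved trees reach 1.  CD deliberately
# violates the triangle inequality; it is an incongruence indicator, not a
# metric, and differs from Robinson-Foulds exactly in being blind to
# resolution.

#' Do two clades conflict?
#'
#' Rooted-clade mode: conflict iff the clades overlap and neither contains
#' the other.  Unrooted-split mode: conflict iff all four intersections of
#' the induced bipartitions are non-empty (the classical split-compatibility
#' test).
#'
#' @param c1,c2 character vectors of tip labels (nontrivial clades).
#' @param full_taxa the complete shared tip set (needed in unrooted mode).
#' @param mode `"rooted"` (default) or `"unrooted"`.
#' @return logical.
#' @export
clades_conflict <- function(c1, c2, full_taxa, mode = c("rooted", "unrooted")) {
  mode <- match.arg(mode)
  if (!all(c1 %in% full_taxa) || !all(c2 %in% full_taxa))
    stop_domain("clade contains labels outside `full_taxa`")
  inter <- length(intersect(c1, c2))
  if (inter == 0L) return(FALSE)
  d12 <- length(setdiff(c1, c2))
  d21 <- length(setdiff(c2, c1))
  if (mode == "rooted") return(d12 > 0L && d21 > 0L)
  outside <- length(full_taxa) - (inter + d12 + d21)
  d12 > 0L && d21 > 0L && outside > 0L
}

#' Contradiction difference between two rooted topologies
#'
#' Prunes both trees to their shared tips, counts the splits of each tree
#' contradicted by at least one split of the other, and normalizes by
#' `2 * (n_shared - 2)`.  Symmetric in its arguments; requires at least 3
#' shared tips.
#'
#' @param treeA,treeB `phylo` objects (or Newick strings).
#' @param mode clade-conflict mode, `"rooted"` (default) or `"unrooted"`;
#'   see [clades_conflict].
#' @return an object of class `cd_result` with fields `n_shared`, `N_AB`,
#'   `N_BA`, `denominator`, `cd`, `mode`.
#' @export
#' @examples
#' a <- parse_newick("((A,B),(C,(D,E)));")
#' b <- parse_newick("((A,C),(B,(D,E)));")
#' contradiction_difference(a, b)
contradiction_difference <- function(treeA, treeB,
                                     mode = c("rooted", "unrooted")) {
  mode <- match.arg(mode)
  if (is.character(treeA)) treeA <- parse_newick(treeA)
  if (is.character(treeB)) treeB <- parse_newick(treeB)
  treeA <- canonicalize_tree(treeA)
  treeB <- canonicalize_tree(treeB)
  shared <- intersect(treeA$tip.label, treeB$tip.label)
  if (length(shared) < 3L)
    stop_domain("trees share only ", length(shared),
                " tips; at least 3 shared tips are required")
  a <- prune_to_taxa(treeA, shared)
  b <- prune_to_taxa(treeB, shared)
  ca <- nontrivial_clades(a)
  cb <- nontrivial_clades(b)
  n_ab <- .count_contradicted(ca, cb, shared, mode)
  n_ba <- .count_contradicted(cb, ca, shared, mode)
  denom <- 2L * (length(shared) - 2L)
  structure(list(n_shared = length(shared), N_AB = n_ab, N_BA = n_ba,
                 denominator = denom, cd = (n_ab + n_ba) / denom,
                 mode = mode),
            class = "cd_result")
}

# number of clades in `from` contradicted by >= 1 clade in `against`
.count_contradicted <- function(from, against, full_taxa, mode) {
  if (!length(from) || !length(against)) return(0L)
  sum(vapply(from, function(c1) {
    any(vapply(against, function(c2)
      clades_conflict(c1, c2, full_taxa, mode), logical(1)))
  }, logical(1)))
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf("CD = %.2f  (N_AB = %d, N_BA = %d, denominator = %d, %d shared tips, %s mode)\n",
              x$cd, x$N_AB, x$N_BA, x$denominator, x$n_shared, x$mode))
  invisible(x)
}

#' Pairwise CD matrix for a set of labeled topologies
#'
#' @param trees named list of `phylo` objects (or Newick strings); names are
#'   used as row/column labels.
#' @param mode see [contradiction_difference].
#' @return a `cd_matrix` object: a symmetric numeric matrix of CD values with
#'   zero diagonal (`NA` for pairs sharing fewer than 3 tips, reported as
#'   undefined rather than 0), with the full `cd_result` objects in
#'   attribute `"results"`.
#' @export
cd_matrix <- function(trees, mode = c("rooted", "unrooted")) {
  mode <- match.arg(mode)
  if (length(trees) < 2L) stop_domain("need at least 2 trees")
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    names(trees) <- paste0("tree", seq_along(trees))
  trees <- lapply(trees, function(t)
    if (is.character(t)) parse_newick(t) else canonicalize_tree(t))
  k <- length(trees)
  m <- matrix(0, k, k, dimnames = list(names(trees), names(trees)))
  results <- list()
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    res <- tryCatch(contradiction_difference(trees[[i]], trees[[j]], mode),
                    error = function(e) NULL)
    if (is.null(res)) {
      m[i, j] <- m[j, i] <- NA_real_
    } else {
      m[i, j] <- m[j, i] <- res$cd
      results[[paste(names(trees)[i], names(trees)[j], sep = " vs ")]] <- res
    }
  }
  structure(m, class = c("cd_matrix", "matrix"), results = results)
}

#' Render a CD matrix as an upper-triangle table
#'
#' Values rounded to two decimals only at render time; lower triangle and
#' diagonal left blank.  Undefined pairs (fewer than 3 shared tips) render
#' as `"undef"`.
#'
#' @param x a [cd_matrix] result.
#' @param digits decimal places (default 2).
#' @return a character matrix suitable for `write.table`.
#' @export
format_cd_matrix <- function(x, digits = 2) {
  stopifnot(inherits(x, "cd_matrix"))
  k <- nrow(x)
  out <- matrix("", k, k, dimnames = dimnames(x))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k))
    out[i, j] <- if (is.na(x[i, j])) "undef" else
      formatC(round(x[i, j], digits), format = "f", digits = digits)
  out
}

#' @export
print.cd_matrix <- function(x, ...) {
  print(format_cd_matrix(x), quote = FALSE)
  invisible(x)
}
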