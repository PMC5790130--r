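# Parsimony lengths on (possibly multifurcating) rooted trees and
# consistency-index profiling.
#
# Lengths use Hartigan's generalization of the Fitch two-pass count, which
# is exact on multifurcating trees for unordered characters: at each
# internal node, with k(s) = number of children whose state sets contain s
# and K = max k(s), the node keeps {s : k(s) = K} and adds
# (number of children - K) changes.  Tips with MISSING/INAPPLICABLE cells
# carry the full state set and never force changes.  Polytomies are treated
# as hard: changes are counted on the tree as given, which is what a CI
# profile on a half-compatibility summary (a polytomous tree) requires.

#' Parsimony length of one character on a rooted tree
#'
#' @param tree a `phylo` object (polytomies allowed); tips absent from
#'   `states` behave as missing.
#' @param states named character vector: taxon label -> cell value
#'   (state symbol, `"?"` or `"-"`).
#' @param alphabet symbols counted as real states; default: all observed
#'   non-missing values.
#' @return integer: minimum number of state changes.
#' @export
parsimony_length <- function(tree, states, alphabet = NULL) {
  tree <- canonicalize_tree(tree)
  if (is.null(names(states))) stop_domain("`states` must be named by taxon")
  if (is.null(alphabet))
    alphabet <- setdiff(unique(states), c(MISSING_CELL, INAPP_CELL))
  eff <- .effective_states(states, alphabet)
  observed <- sort(unique(eff[!is.na(eff)]))
  if (length(observed) <= 1L) return(0L)
  n <- ape::Ntip(tree)
  kids <- .children_of(tree)
  k <- length(observed)
  sets <- matrix(FALSE, n + tree$Nnode, k)  # node x state membership
  for (i in seq_len(n)) {
    s <- eff[tree$tip.label[i]]
    if (is.null(s) || is.na(s)) sets[i, ] <- TRUE
    else sets[i, match(s, observed)] <- TRUE
  }
  cost <- 0L
  for (v in rev(.preorder_nodes(tree, kids))) {
    ch <- kids[[v]]
    if (!length(ch)) next
    counts <- colSums(sets[ch, , drop = FALSE])
    K <- max(counts)
    sets[v, ] <- counts == K
    cost <- cost + length(ch) - K
  }
  as.integer(cost)
}

#' Consistency index of one character on a tree
#'
#' `ci = m / s` where `m` = distinct observed (non-missing) states minus 1
#' and `s` = parsimony length on the tree.  Undefined (NA) when `s = 0`
#' (constant or effectively constant column).
#'
#' @inheritParams parsimony_length
#' @return numeric in (0, 1], or `NA` when undefined.
#' @export
consistency_index <- function(tree, states, alphabet = NULL) {
  if (is.null(alphabet))
    alphabet <- setdiff(unique(states), c(MISSING_CELL, INAPP_CELL))
  eff <- .effective_states(states, alphabet)
  m <- max(0L, length(unique(eff[!is.na(eff)])) - 1L)
  s <- parsimony_length(tree, states, alphabet)
  if (s == 0L) return(NA_real_)
  m / s
}

#' Per-character consistency-index report with ensemble CI
#'
#' For each selected column: `m` (minimum conceivable steps), `s` (steps on
#' the tree), `ci = m/s`, plus the ensemble (composite) consistency index
#' `sum(m) / sum(s)` over the columns with `s > 0`.  Columns with `s = 0`
#' are excluded from the ensemble sums and flagged; autapomorphic columns
#' (ci = 1 by construction) are flagged as uninformative.
#'
#' @param tree a `phylo` object.
#' @param x a [char_matrix].
#' @param ids column ids to profile (default all).
#' @param exclude_ids column ids to drop from the ensemble (e.g. characters
#'   whose high consistency is a missing-data artifact); they still appear
#'   in the per-column table.
#' @return an object of class `ci_report`: data.frame with columns `id`,
#'   `m`, `s`, `ci`, `informative`, `in_ensemble`, and the ensemble value in
#'   attribute `"ensemble_ci"`.
#' @export
ci_report <- function(tree, x, ids = NULL, exclude_ids = integer(0)) {
  stopifnot(inherits(x, "char_matrix"))
  tree <- canonicalize_tree(tree)
  if (is.null(ids)) ids <- x$col_id
  sub <- subset_matrix(x, ids = ids)
  rows <- lapply(seq_len(ncol(sub$cells)), function(j) {
    states <- setNames(sub$cells[, j], rownames(sub$cells))
    alpha <- sub$alphabets[[sub$partition[j]]]
    eff <- .effective_states(states, alpha)
    m <- max(0L, length(unique(eff[!is.na(eff)])) - 1L)
    s <- parsimony_length(tree, states, alpha)
    data.frame(id = sub$col_id[j], m = m, s = s,
               ci = if (s > 0L) m / s else NA_real_,
               informative = is_parsimony_informative(states, alpha))
  })
  out <- do.call(rbind, rows)
  out$in_ensemble <- out$s > 0L & !(out$id %in% exclude_ids)
  if (!any(out$in_ensemble))
    stop_domain("no columns with s > 0 in the requested subset")
  ens <- sum(out$m[out$in_ensemble]) / sum(out$s[out$in_ensemble])
  structure(out, ensemble_ci = ens, class = c("ci_report", "data.frame"))
}

#' @export
print.ci_report <- function(x, ...) {
  NextMethod()
  cat(sprintf("ensemble CI (sum m / sum s over %d columns): %.3f\n",
              sum(x$in_ensemble), attr(x, "ensemble_ci")))
  invisible(x)
}

# ---- exhaustive search oracle ---------------------------------------------

# enumerate all fully resolved rooted topologies as nested lists
# (leaf = label, internal = list of two subtrees); (2n-3)!! trees
.enumerate_rooted <- function(taxa) {
  insert_all <- function(tree, leaf) {
    res <- list(list(tree, leaf))  # above the current root
    if (is.list(tree)) {
      for (i in 1:2) {
        for (sub in insert_all(tree[[i]], leaf)) {
          t2 <- tree
          t2[[i]] <- sub
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  trees <- list(taxa[[1]])
  for (tx in taxa[-1]) trees <- unlist(lapply(trees, insert_all, leaf = tx),
                                       recursive = FALSE)
  trees
}

.nested_to_newick <- function(tree) {
  rec <- function(t)
    if (is.list(t)) paste0("(", rec(t[[1]]), ",", rec(t[[2]]), ")")
    else .quote_label(t)
  paste0(rec(tree), ";")
}

# Fitch length of one character on a nested binary tree; states_env maps
# taxon -> integer state index or NA (missing)
.fitch_nested <- function(tree, states, k) {
  cost <- 0L
  rec <- function(t) {
    if (!is.list(t)) {
      s <- states[[t]]
      if (is.null(s) || is.na(s)) return(rep(TRUE, k))
      v <- rep(FALSE, k); v[s] <- TRUE
      return(v)
    }
    a <- rec(t[[1]]); b <- rec(t[[2]])
    both <- a & b
    if (any(both)) both else { cost <<- cost + 1L; a | b }
  }
  rec(tree)
  cost
}

#' Exhaustive maximum-parsimony search (test oracle)
#'
#' Enumerates all `(2n-3)!!` fully resolved rooted topologies on the
#' matrix's taxa and returns the optimal set.  Intended as an independent
#' oracle for small instances, not a production search.
#'
#' @param x a [char_matrix].
#' @param max_tips refuse more taxa than this (default 7).
#' @return list with `best_length` and `trees` (list of canonical `phylo`
#'   optima).
#' @export
exhaustive_mp_search <- function(x, max_tips = 7) {
  stopifnot(inherits(x, "char_matrix"))
  taxa <- rownames(x$cells)
  if (length(taxa) > max_tips)
    stop_domain(length(taxa), " taxa exceeds max_tips = ", max_tips)
  if (length(taxa) < 3L) stop_domain("need at least 3 taxa")
  # precompute integer state indices per column
  cols <- lapply(seq_len(ncol(x$cells)), function(j) {
    alpha <- x$alphabets[[x$partition[j]]]
    eff <- .effective_states(x$cells[, j], alpha)
    obs <- sort(unique(eff[!is.na(eff)]))
    if (length(obs) <= 1L) return(NULL)
    list(states = as.list(setNames(match(eff, obs), taxa)), k = length(obs))
  })
  cols <- cols[!vapply(cols, is.null, logical(1))]
  trees <- .enumerate_rooted(as.list(taxa))
  score <- vapply(trees, function(tr)
    sum(vapply(cols, function(cl) .fitch_nested(tr, cl$states, cl$k), 0L)),
    integer(1))
  best <- min(score)
  list(best_length = best,
       trees = lapply(trees[score == best], function(tr)
         parse_newick(.nested_to_newick(tr))))
}
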