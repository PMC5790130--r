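# Homoplasy-free "perfect" characters for partition-size sensitivity
# analyses: binary, parsimony-informative columns, each marking a single
# state shift on one internal node of a chosen topology.  No stochastic
# model is involved: the only randomness is which nodes receive the
# leftover characters after the even-allocation phase.

#' Eligible nodes for perfect-character placement
#'
#' Internal, non-root nodes whose clade size lies in `[2, n-2]`: a shift on
#' a clade of size `n-1` would produce an autapomorphic (uninformative)
#' column on the shared reading of the root, so such nodes are excluded.
#'
#' @param tree a `phylo` object.
#' @return list of clades (sorted character vectors).
#' @export
eligible_nodes <- function(tree) {
  tree <- canonicalize_tree(tree)
  n <- ape::Ntip(tree)
  cl <- nontrivial_clades(tree)
  cl[vapply(cl, length, 1L) <= n - 2L]
}

#' Plan the allocation of perfect characters across eligible nodes
#'
#' Deterministic even phase: every eligible node receives
#' `q = floor(n_chars / k)` characters (`k` eligible nodes).  The
#' `r = n_chars - q * k` leftover characters are assigned to `r` distinct
#' nodes drawn uniformly without replacement under `seed`.  With 54
#' characters and 13 eligible nodes this is the 52-even + 2-random split.
#'
#' @param tree a `phylo` object with at least one eligible node.
#' @param n_chars number of characters to place (>= 1).
#' @param seed RNG seed (used only for the remainder placement).
#' @return an object of class `allocation_plan`: list with `clades`
#'   (eligible clades), `counts` (per-node character counts), `q`, `r`,
#'   `even_total` (`q * k`), `remainder_nodes` (indices), `seed`.
#' @export
plan_allocation <- function(tree, n_chars, seed = 1L) {
  tree <- canonicalize_tree(tree)
  if (!is_scalar_number(n_chars) || n_chars < 1 || n_chars != round(n_chars))
    stop_domain("`n_chars` must be a positive integer")
  clades <- eligible_nodes(tree)
  k <- length(clades)
  if (k == 0L) stop_domain("tree has no eligible nodes (star tree?)")
  n_chars <- as.integer(n_chars)
  q <- n_chars %/% k
  r <- n_chars - q * k
  counts <- rep(q, k)
  rem <- integer(0)
  if (r > 0L) {
    rem <- with_seed(seed, sample.int(k, r, replace = FALSE))
    counts[rem] <- counts[rem] + 1L
  }
  structure(list(clades = clades, counts = counts, q = q, r = r,
                 even_total = q * k, remainder_nodes = sort(rem),
                 seed = seed),
            class = "allocation_plan")
}

#' @export
print.allocation_plan <- function(x, ...) {
  cat(sprintf(
    "allocation_plan: %d characters over %d eligible nodes (q = %d, even phase = %d, remainder = %d)\n",
    sum(x$counts), length(x$clades), x$q, x$even_total, x$r))
  invisible(x)
}

#' Generate a perfect-character matrix from an allocation plan
#'
#' One binary column per planned character: tips inside the node's clade
#' are `1`, tips outside `0`, no missing cells.  Every column is parsimony
#' informative and has parsimony length 1 (hence CI 1) on the generating
#' tree.
#'
#' @param tree the generating `phylo`.
#' @param plan an [plan_allocation] result for `tree`.
#' @return a [char_matrix] (partition `"morphology"`, alphabet `0/1`).
#' @export
generate_perfect_matrix <- function(tree, plan) {
  stopifnot(inherits(plan, "allocation_plan"))
  tree <- canonicalize_tree(tree)
  taxa <- sort(tree$tip.label)
  tree_clades <- vapply(nontrivial_clades(tree), .clade_key, character(1))
  cols <- list()
  for (i in seq_along(plan$clades)) {
    cl <- plan$clades[[i]]
    if (!(.clade_key(cl) %in% tree_clades))
      stop_domain("plan clade {", paste(cl, collapse = ","),
                  "} is not a clade of the tree")
    if (plan$counts[i] == 0L) next
    col <- ifelse(taxa %in% cl, "1", "0")
    for (rep_j in seq_len(plan$counts[i])) cols[[length(cols) + 1L]] <- col
  }
  cells <- do.call(cbind, cols)
  rownames(cells) <- taxa
  char_matrix(cells, partition = "morphology",
              alphabets = list(morphology = c("0", "1")))
}

#' Sensitivity-analysis workflow: perfect morphology + real molecular data
#'
#' For each replicate, re-plans the remainder placement (seed + replicate
#' index), generates the perfect matrix on `base_tree`, combines it with
#' the molecular partition, and optionally writes an analysis-ready NEXUS
#' file per replicate.  Downstream tree inference is external software's
#' job; its tree samples re-enter through [read_trees_nexus],
#' [majority_rule] and [cd_matrix].
#'
#' @param base_tree the topology the perfect characters support.
#' @param n_chars characters per replicate (e.g. 54).
#' @param molecular a [char_matrix] with the molecular partition; its taxa
#'   must include the tree's tips.
#' @param n_replicates number of replicates (default 10).
#' @param seed base RNG seed; replicate i uses `seed + i`.
#' @param out_dir write `replicate_<i>.nex` files here when non-NULL.
#' @return list with `plans`, `matrices` (combined [char_matrix] per
#'   replicate) and `files` (paths, or NULL).
#' @export
sensitivity_workflow <- function(base_tree, n_chars, molecular,
                                 n_replicates = 10, seed = 1L,
                                 out_dir = NULL) {
  base_tree <- canonicalize_tree(base_tree)
  stopifnot(inherits(molecular, "char_matrix"))
  absent <- setdiff(base_tree$tip.label, rownames(molecular$cells))
  if (length(absent))
    stop_domain("tree tips absent from molecular matrix: ",
                paste(absent, collapse = ", "))
  plans <- list(); mats <- list(); files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(n_replicates)
  }
  for (i in seq_len(n_replicates)) {
    plan <- plan_allocation(base_tree, n_chars, seed = seed + i)
    morph <- generate_perfect_matrix(base_tree, plan)
    comb <- combine_partitions(morph, molecular)
    plans[[i]] <- plan
    mats[[i]] <- comb
    if (!is.null(out_dir)) {
      files[i] <- file.path(out_dir, sprintf("replicate_%02d.nex", i))
      write_nexus_matrix(comb, files[i])
    }
  }
  list(plans = plans, matrices = mats, files = files)
}
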