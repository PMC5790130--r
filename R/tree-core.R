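# Rooted-tree substrate.
#
# Trees are `ape::phylo` objects, always handled ROOTED: every analysis in
# this package counts rooted clades (sets of tip labels below an internal
# node), the denominator 2*(n-2) of the contradiction difference being the
# number of non-root internal nodes of two fully resolved rooted trees.
# Branch lengths and support annotations are parsed but ignored by every
# computation.

# ---- canonical form -------------------------------------------------------

# children lists indexed by node number (tips 1..n, internals n+1..)
.children_of <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  kids
}

.root_of <- function(tree) ape::Ntip(tree) + 1L

# per-node sorted tip-label sets, list indexed by node number
.node_clades <- function(tree) {
  n <- ape::Ntip(tree)
  kids <- .children_of(tree)
  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  # postorder: process nodes in an order where children come first
  ord <- rev(.preorder_nodes(tree, kids))
  for (v in ord) {
    if (v <= n) sets[[v]] <- tree$tip.label[v]
    else sets[[v]] <- sort(unlist(sets[kids[[v]]], use.names = FALSE))
  }
  sets
}

.preorder_nodes <- function(tree, kids = .children_of(tree)) {
  stack <- .root_of(tree)
  out <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  out
}

.quote_label <- function(x) {
  needs <- grepl("[]\t ()[{}/\\,;:=*'\"`+<>-]", x)
  ifelse(needs, paste0("'", gsub("'", "''", x), "'"), x)
}

#' Canonicalize a rooted tree
#'
#' Suppresses unary (single-child) internal nodes and rotates every node so
#' that children are ordered by the smallest tip label they contain, giving a
#' deterministic serialization.  Validates that tip labels are unique and
#' nonempty.  Branch lengths are dropped (all computations in this package
#' are purely topological).
#'
#' @param tree an `ape::phylo` object.
#' @return a canonical `phylo` object.
#' @export
canonicalize_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # unquote labels ('A x' -> A x); ape keeps Newick quotes verbatim
  labs <- tree$tip.label
  quoted <- grepl("^'.*'$", labs)
  labs[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", labs[quoted]))
  tree$tip.label <- labs
  if (anyNA(labs) || any(!nzchar(labs)))
    stop_domain("tip labels must be nonempty")
  if (anyDuplicated(labs))
    stop_domain("duplicate tip labels: ",
                paste(unique(labs[duplicated(labs)]), collapse = ", "))
  tree <- ape::collapse.singles(tree)
  tree$edge.length <- NULL
  .rebuild_canonical(tree)
}

# rebuild the phylo with children sorted by smallest contained tip label and
# standard preorder numbering; avoids round-tripping labels through Newick
.rebuild_canonical <- function(tree) {
  n <- ape::Ntip(tree)
  kids <- .children_of(tree)
  sets <- .node_clades(tree)
  edges <- integer(0)
  tip_lab <- character(n)
  tip_next <- 0L
  int_next <- n + 1L
  new_id <- integer(n + tree$Nnode)
  rec <- function(v) {  # v already numbered; emits edges in preorder
    ch <- kids[[v]]
    ch <- ch[order(vapply(ch, function(c2) sets[[c2]][1L], character(1)),
                   method = "radix")]
    for (c2 in ch) {
      if (!length(kids[[c2]])) {
        tip_next <<- tip_next + 1L
        new_id[c2] <<- tip_next
        tip_lab[tip_next] <<- tree$tip.label[c2]
        edges <<- c(edges, new_id[v], new_id[c2])
      } else {
        int_next <<- int_next + 1L
        new_id[c2] <<- int_next - 1L
        edges <<- c(edges, new_id[v], new_id[c2])
        rec(c2)
      }
    }
    invisible()
  }
  root <- .root_of(tree)
  new_id[root] <- n + 1L
  int_next <- n + 2L
  rec(root)
  out <- list(edge = matrix(edges, ncol = 2, byrow = TRUE),
              tip.label = tip_lab, Nnode = tree$Nnode)
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  out
}

.serialize_canonical <- function(tree, annotations = NULL) {
  n <- ape::Ntip(tree)
  kids <- .children_of(tree)
  sets <- .node_clades(tree)
  rec <- function(v) {
    if (v <= n) return(.quote_label(tree$tip.label[v]))
    ch <- kids[[v]]
    key <- vapply(ch, function(c2) sets[[c2]][1L], character(1))
    ch <- ch[order(key, method = "radix")]
    lab <- if (!is.null(annotations)) annotations[v - n] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", lab)
  }
  paste0(rec(.root_of(tree)), ";")
}

# ---- Newick I/O -----------------------------------------------------------

#' Parse a Newick string into a rooted tree
#'
#' Accepts multifurcating Newick with optional branch lengths, support values
#' and quoted labels; the result is canonicalized ([canonicalize_tree]) and
#' treated as rooted.
#'
#' @param text a single Newick string terminated by `;`.
#' @return a canonical `phylo` object.
#' @export
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' nontrivial_clades(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop_domain("empty Newick string")
  if (!grepl(";\\s*$", text))
    stop_domain("Newick parse error at position ", nchar(text),
                ": missing terminating ';'")
  # balance check with position reporting (ignoring quoted segments)
  depth <- 0L
  in_quote <- FALSE
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop_domain("Newick parse error at position ", i,
                    ": unmatched ')'")
    }
  }
  if (in_quote) stop_domain("Newick parse error: unterminated quote")
  if (depth != 0L)
    stop_domain("Newick parse error at position ", nchar(text),
                ": ", depth, " unclosed '('")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop_domain("Newick parse error: ape could not read the string")
  canonicalize_tree(tr)
}

#' Serialize a rooted tree to canonical Newick
#'
#' Children are written in canonical order (smallest contained tip label
#' first); branch lengths are omitted.
#'
#' @param tree a `phylo` object.
#' @param annotations optional character vector of internal-node labels
#'   (length `tree$Nnode`), e.g. consensus clade frequencies.
#' @return a Newick string.
#' @export
write_newick <- function(tree, annotations = NULL) {
  tree <- canonicalize_tree(tree)
  if (!is.null(annotations)) {
    stopifnot(length(annotations) == tree$Nnode)
    # annotations follow node numbering of the canonical tree
  }
  .serialize_canonical(tree, annotations = annotations)
}

# ---- NEXUS trees ----------------------------------------------------------

#' Read trees from a NEXUS TREES block
#'
#' Backed by [ape::read.nexus] (TRANSLATE tables, MrBayes / PAUP dialects).
#' Trees flagged `[&U]` (unrooted) are still interpreted as rooted, with a
#' warning, matching the package-wide rooted reading.
#'
#' @param file path to a NEXUS file, or `NULL` if `text` is given.
#' @param text NEXUS document as a single string (alternative to `file`).
#' @param burnin_frac fraction of initial trees to discard (MrBayes `.t`
#'   convention), default 0.
#' @param source tag recorded on the returned sample.
#' @return a [tree_sample].
#' @export
read_trees_nexus <- function(file = NULL, text = NULL, burnin_frac = 0,
                             source = "unspecified") {
  if (is.null(file) == is.null(text))
    stop_domain("supply exactly one of `file` or `text`")
  if (!is.null(text)) {
    file <- tempfile(fileext = ".nex")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  raw <- paste(readLines(file, warn = FALSE), collapse = "\n")
  if (!grepl("begin\\s+trees", raw, ignore.case = TRUE))
    stop_domain("no TREES block found in NEXUS input")
  if (!grepl("\\btree\\b[^=;]*=", raw, ignore.case = TRUE))
    stop_domain("TREES block contains no trees")
  if (grepl("\\[\\s*&\\s*U\\s*\\]", raw, ignore.case = TRUE))
    warning("input contains trees flagged [&U] (unrooted); ",
            "interpreting as rooted", call. = FALSE)
  trees <- ape::read.nexus(file, force.multi = TRUE)
  trees <- lapply(trees, canonicalize_tree)
  if (burnin_frac > 0) {
    stopifnot(burnin_frac < 1)
    drop <- floor(burnin_frac * length(trees))
    if (drop > 0) trees <- trees[-seq_len(drop)]
  }
  tree_sample(trees, source = source)
}

# ---- pruning and clades ---------------------------------------------------

#' Restrict a tree to a subset of its tips
#'
#' Drops all tips not in `keep` and suppresses the unary nodes this creates,
#' so the result's clade set is exactly the nontrivial intersections of the
#' input's clades with `keep`.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return a canonical `phylo` on exactly `keep`.
#' @export
prune_to_taxa <- function(tree, keep) {
  tree <- canonicalize_tree(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop_domain("unknown tip labels: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L)
    stop_domain("`keep` must contain at least 2 tip labels")
  if (setequal(keep, tree$tip.label)) return(tree)
  canonicalize_tree(ape::keep.tip(tree, keep))
}

#' Nontrivial rooted clades of a tree
#'
#' Returns the tip-label sets of all internal non-root nodes, i.e. clades of
#' size 2 to n-1.  A fully resolved rooted tree on n tips yields exactly
#' n-2 clades; a star tree yields none.
#'
#' @param tree a `phylo` object with at least 3 tips.
#' @return a list of sorted character vectors.
#' @export
nontrivial_clades <- function(tree) {
  tree <- canonicalize_tree(tree)
  n <- ape::Ntip(tree)
  if (n < 3L) stop_domain("tree must have at least 3 tips")
  sets <- .node_clades(tree)
  idx <- setdiff(seq.int(n + 1L, n + tree$Nnode), .root_of(tree))
  out <- sets[idx]
  out[vapply(out, length, 1L) <= n - 1L]  # sizes are >= 2 by construction
}

#' Normalize tip labels
#'
#' Optional helper (off by default everywhere): trims whitespace and maps
#' underscores to spaces, for reconciling labels across files.  Comparison
#' in all package operations is otherwise exact and case-sensitive.
#'
#' @param x character vector of labels, or a `phylo` object.
#' @return same type as `x` with normalized labels.
#' @export
normalize_labels <- function(x) {
  norm <- function(s) trimws(gsub("_", " ", s, fixed = TRUE))
  if (inherits(x, "phylo")) {
    x$tip.label <- norm(x$tip.label)
    return(canonicalize_tree(x))
  }
  norm(x)
}

# ---- tree samples ---------------------------------------------------------

#' Construct a sample of trees over a common tip set
#'
#' @param trees list of `phylo` objects (all over the same tip-label set),
#'   or a `multiPhylo`.
#' @param weights positive per-tree weights, recycled; default 1.
#' @param source tag: `"posterior"`, `"parsimony"`, `"simulated"` or other.
#' @return an object of class `tree_sample`.
#' @export
tree_sample <- function(trees, weights = 1, source = "unspecified") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(unclass(trees), canonicalize_tree)
  if (!length(trees)) stop_domain("empty tree sample")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop_domain("tree ", i, " has a different tip set than tree 1")
  weights <- rep_len(as.numeric(weights), length(trees))
  if (any(weights <= 0) || anyNA(weights))
    stop_domain("weights must be positive")
  structure(list(trees = trees, weights = weights, source = source),
            class = "tree_sample")
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' @export
print.tree_sample <- function(x, ...) {
  cat("tree_sample:", length(x$trees), "trees on",
      ape::Ntip(x$trees[[1]]), "tips (source:", x$source, ")\n")
  invisible(x)
}
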