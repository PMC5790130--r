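# Independent oracles and fixture builders.  These deliberately avoid the
# package's own code paths: clade extraction goes through ape::prop.part,
# conflict testing and parsimony minimization are written from first
# principles, so a bug in the implementation cannot hide in its oracle.

random_resolved_tree <- function(n, seed) simulate_tree(n, seed = seed)

# --- brute-force conflict count (oracle for contradiction_difference) ------

# clades via ape::prop.part (includes the root clade, which we drop)
oracle_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sets <- lapply(pp, function(i) sort(labs[i]))
  sets[vapply(sets, length, 1L) < ape::Ntip(tree)]
}

oracle_conflict <- function(c1, c2, taxa, mode = "rooted") {
  i <- intersect(c1, c2)
  if (!length(i)) return(FALSE)
  only1 <- setdiff(c1, c2); only2 <- setdiff(c2, c1)
  if (mode == "rooted") return(length(only1) > 0 && length(only2) > 0)
  out <- setdiff(taxa, union(c1, c2))
  length(only1) > 0 && length(only2) > 0 && length(out) > 0
}

oracle_cd <- function(a, b, mode = "rooted") {
  shared <- intersect(a$tip.label, b$tip.label)
  a <- ape::keep.tip(a, shared); b <- ape::keep.tip(b, shared)
  ca <- oracle_clades(a); cb <- oracle_clades(b)
  n_ab <- sum(vapply(ca, function(x)
    any(vapply(cb, function(y) oracle_conflict(x, y, shared, mode),
               logical(1))), logical(1)))
  n_ba <- sum(vapply(cb, function(x)
    any(vapply(ca, function(y) oracle_conflict(x, y, shared, mode),
               logical(1))), logical(1)))
  list(N_AB = n_ab, N_BA = n_ba,
       cd = (n_ab + n_ba) / (2 * (length(shared) - 2)))
}

# --- exhaustive parsimony (oracle for Hartigan lengths) --------------------

# minimum changes over all assignments of observed states to internal nodes
oracle_parsimony <- function(tree, states) {
  tree <- ape::collapse.singles(tree)
  n <- ape::Ntip(tree)
  eff <- states[tree$tip.label]
  eff[eff %in% c("?", "-")] <- NA
  obs <- sort(unique(eff[!is.na(eff)]))
  k <- length(obs)
  if (k <= 1) return(0L)
  nn <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  tip_state <- match(eff, obs)  # NA = free tip
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    changes <- 0
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      sa <- assign_int[a - n]
      sb <- if (b <= n) tip_state[b] else assign_int[b - n]
      if (!is.na(sb) && sb != sa) changes <- changes + 1
    }
    if (changes < best) best <- changes
  }
  as.integer(best)
}

# --- misc fixtures ---------------------------------------------------------

toy_matrix <- function(cells_by_row, partition = "morphology") {
  cells <- do.call(rbind, cells_by_row)
  rownames(cells) <- names(cells_by_row)
  char_matrix(cells, partition = partition)
}

# rooted tree with exactly 13 eligible nodes: 13 cherries on a root polytomy
tree_13_nodes <- function() {
  cherries <- paste0("(", letters[1:13], "1,", letters[1:13], "2)")
  parse_newick(paste0("(", paste(cherries, collapse = ","), ");"))
}

# is the unrooted split induced by `clade` present in `tree` (as the clade
# itself or its complement)?
split_in_tree <- function(tree, clade) {
  taxa <- sort(tree$tip.label)
  keys <- vapply(nontrivial_clades(tree), paste, "", collapse = "|")
  key <- function(s) paste(sort(s), collapse = "|")
  key(clade) %in% keys || key(setdiff(taxa, clade)) %in% keys
}

# two fully resolved rooted 18-tip trees identical except for one
# three-taxon resolution: ((X,Y),Z) vs ((X,Z),Y)
triplet_shift_pair <- function() {
  backbone <- "(t01,(t02,(t03,(t04,(t05,(t06,(t07,(t08,(t09,(t10,(t11,(t12,(t13,(t14,(t15,%s)))))))))))))));"
  list(a = parse_newick(sprintf(backbone, "((X,Y),Z)")),
       b = parse_newick(sprintf(backbone, "((X,Z),Y)")))
}
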