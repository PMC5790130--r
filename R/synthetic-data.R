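# Synthetic data with the statistical structure the pipeline assumes:
# Yule tree shapes, NNI-perturbed tree samples standing in for posterior /
# most-parsimonious tree sets, Mk-evolved discrete matrices with optional
# conditioning on parsimony-informativeness (the morphological
# ascertainment convention), i.i.d. cell missingness, and a study-like
# combined dataset: 26 taxa (4 inarticulate-like outgroups, 2
# terebratulide-like outgroups, 20 ingroup rows including one congeneric
# species pair with identical morphology), a 66-column multistate
# morphological partition with realistic per-taxon missingness, and a
# 3435-site 4-state molecular partition covering only 18 taxa.  Everything
# here is SYNTHETIC: it emulates dataset shape, not real brachiopods.

#' Simulate a fully resolved rooted topology
#'
#' @param n_tips number of tips (>= 3).
#' @param model `"yule"` (default; pure-birth shape via [ape::rphylo]) or
#'   `"uniform"` (uniform over labelled topologies via [ape::rtopology]).
#' @param seed RNG seed (mandatory).
#' @param labels optional tip labels (length `n_tips`); default
#'   `t01, t02, ...`.
#' @return a canonical `phylo`.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "uniform"), seed,
                          labels = NULL) {
  model <- match.arg(model)
  if (!is_scalar_number(n_tips) || n_tips < 3)
    stop_domain("`n_tips` must be >= 3")
  n_tips <- as.integer(n_tips)
  if (is.null(labels))
    labels <- sprintf("t%02d", seq_len(n_tips))
  stopifnot(length(labels) == n_tips)
  tr <- with_seed(seed, {
    t0 <- if (model == "yule") ape::rphylo(n_tips, birth = 1, death = 0)
          else ape::rtopology(n_tips, rooted = TRUE)
    t0$tip.label <- sample(labels)  # random attachment of labels to shape
    t0
  })
  canonicalize_tree(tr)
}

#' NNI-perturbed tree sample
#'
#' Each sampled tree is the input after `n_nni` random rooted
#' nearest-neighbor interchanges (swap a node's child with the node's
#' sibling); one NNI changes exactly one clade of a resolved tree.
#' `n_nni = 0` returns copies, so the consensus recovers the input exactly.
#' Stands in for posterior / most-parsimonious tree samples when external
#' inference is not run.
#'
#' @param tree a fully resolved `phylo`.
#' @param sample_size number of trees.
#' @param n_nni NNI moves per sampled tree (>= 0).
#' @param seed RNG seed.
#' @return a [tree_sample] with source `"simulated"`.
#' @export
perturb_tree_sample <- function(tree, sample_size, n_nni, seed) {
  tree <- canonicalize_tree(tree)
  if (!ape::is.binary(tree))
    stop_domain("input tree must be fully resolved")
  if (n_nni < 0) stop_domain("`n_nni` must be >= 0")
  trees <- with_seed(seed, lapply(seq_len(sample_size), function(i) {
    tr <- tree
    for (m in seq_len(n_nni)) tr <- .one_nni(tr)
    tr
  }))
  tree_sample(lapply(trees, canonicalize_tree), source = "simulated")
}

# one random rooted NNI on a resolved phylo (edge-matrix surgery)
.one_nni <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  internals <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  v <- if (length(internals) == 1L) internals else sample(internals, 1L)
  edge <- tree$edge
  u <- edge[edge[, 2] == v, 1]              # parent of v
  sib <- setdiff(edge[edge[, 1] == u, 2], v)
  if (length(sib) > 1L) sib <- sample(sib, 1L)
  ch <- edge[edge[, 1] == v, 2]
  c1 <- if (length(ch) == 1L) ch else sample(ch, 1L)
  i_sib <- which(edge[, 1] == u & edge[, 2] == sib)
  i_c1 <- which(edge[, 1] == v & edge[, 2] == c1)
  edge[i_sib, 2] <- c1
  edge[i_c1, 2] <- sib
  tree$edge <- edge
  tree
}

#' Simulate discrete characters under a symmetric Markov (Mk) model
#'
#' Characters evolve independently along the tree under a k-state
#' symmetric model: substitution events are Poisson on each branch (all
#' branches weighted equally) with the rate scaled so the expected total
#' number of events per character equals `expected_changes`; each event
#' moves to one of the other `k - 1` states uniformly.  With
#' `condition_informative = TRUE`, columns that are not parsimony
#' informative are rejected and redrawn (the ascertainment convention for
#' morphological matrices), up to `max_tries` attempts per column.
#'
#' @param tree a `phylo` object.
#' @param n_chars number of columns.
#' @param n_states states per column; scalar or vector recycled over
#'   columns.
#' @param expected_changes expected substitution events per character
#'   (> 0); the homoplasy dial.
#' @param seed RNG seed.
#' @param condition_informative reject non-informative columns (default
#'   TRUE).
#' @param alphabet symbols to use (default `"0", "1", ...`); supply
#'   `c("A","C","G","T")` with `n_states = 4` for a molecular partition.
#' @param partition partition tag for the result (default `"morphology"`).
#' @param max_tries rejection cap per column (default 1000).
#' @return a [char_matrix].
#' @export
simulate_mk_matrix <- function(tree, n_chars, n_states = 2,
                               expected_changes = 2, seed,
                               condition_informative = TRUE,
                               alphabet = NULL, partition = "morphology",
                               max_tries = 1000L) {
  tree <- canonicalize_tree(tree)
  if (any(n_states < 2)) stop_domain("`n_states` must be >= 2")
  if (expected_changes <= 0) stop_domain("`expected_changes` must be > 0")
  n_states <- rep_len(as.integer(n_states), n_chars)
  kmax <- max(n_states)
  if (is.null(alphabet)) alphabet <- as.character(seq_len(kmax) - 1L)
  stopifnot(length(alphabet) >= kmax)
  n <- ape::Ntip(tree)
  kids <- .children_of(tree)
  pre <- .preorder_nodes(tree, kids)
  parent <- integer(n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  n_edges <- nrow(tree$edge)
  mu <- expected_changes / n_edges   # events per branch

  draw_col <- function(k) {
    states <- integer(n + tree$Nnode)
    states[.root_of(tree)] <- sample.int(k, 1L)
    for (v in pre[-1L]) {
      s <- states[parent[v]]
      nev <- stats::rpois(1L, mu)
      if (nev > 0L) for (e in seq_len(nev)) {
        s <- sample(setdiff(seq_len(k), s), 1L)
      }
      states[v] <- s
    }
    alphabet[states[seq_len(n)]]
  }

  cells <- with_seed(seed, {
    out <- matrix(NA_character_, n, n_chars,
                  dimnames = list(tree$tip.label, NULL))
    for (j in seq_len(n_chars)) {
      k <- n_states[j]
      for (try in seq_len(max_tries)) {
        col <- draw_col(k)
        if (!condition_informative ||
            is_parsimony_informative(col, alphabet[seq_len(k)])) break
        if (try == max_tries)
          stop_domain("rejection cap exceeded: expected_changes too low to ",
                      "yield parsimony-informative characters")
      }
      out[, j] <- col
    }
    out
  })
  al <- list(alphabet[seq_len(kmax)])
  names(al) <- partition
  char_matrix(cells, partition = partition, alphabets = al)
}

#' Mask cells to MISSING at per-taxon rates
#'
#' Cells are masked independently (i.i.d. within a taxon/partition) at the
#' given fraction.  A `block` option deletes one contiguous run of columns
#' instead, mimicking a large sequence deletion.
#'
#' @param x a [char_matrix].
#' @param fractions named numeric vector (taxon -> fraction in `[0,1]`,
#'   applied to all partitions) or data.frame with columns `taxon`,
#'   `partition`, `fraction`.
#' @param seed RNG seed.
#' @param block if TRUE, mask one contiguous column block of the required
#'   length instead of i.i.d. cells.
#' @return a [char_matrix].
#' @export
apply_missingness <- function(x, fractions, seed, block = FALSE) {
  stopifnot(inherits(x, "char_matrix"))
  if (is.numeric(fractions) && !is.null(names(fractions)))
    fractions <- data.frame(taxon = rep(names(fractions),
                                        each = length(unique(x$partition))),
                            partition = rep(unique(x$partition),
                                            length(fractions)),
                            fraction = rep(as.numeric(fractions),
                                           each = length(unique(x$partition))))
  stopifnot(all(c("taxon", "partition", "fraction") %in% names(fractions)))
  if (any(fractions$fraction < 0 | fractions$fraction > 1))
    stop_domain("fractions must be in [0, 1]")
  unknown <- setdiff(fractions$taxon, rownames(x$cells))
  if (length(unknown))
    stop_domain("unknown taxa in profile: ", paste(unknown, collapse = ", "))
  cells <- x$cells
  with_seed(seed, {
    for (i in seq_len(nrow(fractions))) {
      tx <- fractions$taxon[i]
      cols <- which(x$partition == fractions$partition[i])
      f <- fractions$fraction[i]
      if (f == 0 || !length(cols)) next
      if (block) {
        len <- round(f * length(cols))
        if (len > 0) {
          start <- sample.int(length(cols) - len + 1L, 1L)
          cells[tx, cols[seq.int(start, start + len - 1L)]] <- MISSING_CELL
        }
      } else {
        hit <- runif(length(cols)) < f
        cells[tx, cols[hit]] <- MISSING_CELL
      }
    }
  })
  char_matrix(cells, x$partition, x$col_id, x$alphabets)
}

# ---- study-like fixture ----------------------------------------------------

#' Default configuration for the study-like synthetic dataset
#'
#' The stated world: 26 species in 25 genera (4 inarticulate-like
#' outgroups, 2 terebratulide-like outgroups, 19 ingroup genera of which
#' one carries a congeneric species pair with identical morphology); a
#' 66-column unordered multistate morphological partition (state counts
#' 2/3/4 with probabilities 0.80/0.15/0.05, matching 66 characters holding
#' ~147 states) conditioned on parsimony-informativeness; a 3435-site
#' 4-state molecular partition restricted to 18 covered species; per-taxon
#' missingness echoing the empirical profile (outgroup morphology ~68-77%
#' missing; three covered taxa missing >50% of sequence).
#'
#' @param n_mol_sites molecular sites (default 3435).
#' @param n_morph_chars morphological columns (default 66).
#' @param morph_expected_changes Mk homoplasy level for morphology
#'   (default 2).
#' @param mol_expected_changes per-site expected changes for the molecular
#'   partition (default 0.3: mostly invariant sites).
#' @param sample_size trees per posterior-like sample (default 50).
#' @param n_nni perturbation strength of the samples (default 1).
#' @return a list of class `synthetic_config`.
#' @export
study_config <- function(n_mol_sites = 3435, n_morph_chars = 66,
                         morph_expected_changes = 2,
                         mol_expected_changes = 0.3,
                         sample_size = 50, n_nni = 1) {
  inart <- sprintf("inart_%d", 1:4)
  tereb <- sprintf("tereb_%d", 1:2)
  rhynch <- sprintf("rhynch_%02d", 1:19)
  species_map <- list(rhynch_01 = c("rhynch_01a", "rhynch_01b"))
  genera <- c(inart, tereb, rhynch)
  species <- unlist(lapply(genera, function(g)
    if (g %in% names(species_map)) species_map[[g]] else g))
  # molecular coverage: all outgroups + both congenerics + 10 more ingroup
  coverage <- c(inart, tereb, "rhynch_01a", "rhynch_01b",
                sprintf("rhynch_%02d", 2:11))
  morph_missing <- setNames(rep(0.06, length(genera)), genera)
  morph_missing[inart] <- c(0.68, 0.77, 0.71, 0.73)
  morph_missing[tereb] <- c(0.12, 0.17)
  morph_missing[c("rhynch_02", "rhynch_03", "rhynch_04")] <- c(0.12, 0.18, 0.11)
  mol_missing <- setNames(rep(0, length(coverage)), coverage)
  mol_missing[c("rhynch_02", "rhynch_03", "rhynch_04")] <- c(0.51, 0.66, 0.51)
  mol_missing[c("rhynch_01a", "rhynch_01b", "tereb_1")] <- c(0.41, 0.46, 0.26)
  structure(list(genera = genera, species = species,
                 species_map = species_map, coverage = coverage,
                 n_morph_chars = n_morph_chars, n_mol_sites = n_mol_sites,
                 morph_state_probs = c(`2` = 0.80, `3` = 0.15, `4` = 0.05),
                 morph_expected_changes = morph_expected_changes,
                 mol_expected_changes = mol_expected_changes,
                 morph_missing = morph_missing, mol_missing = mol_missing,
                 sample_size = sample_size, n_nni = n_nni),
            class = "synthetic_config")
}

#' Generate the full study-like synthetic dataset
#'
#' Returns a generating species tree (outgroup clade sister to the rest),
#' a genus-level morphological matrix expanded to species level (the
#' congeneric pair getting identical rows), a molecular matrix over the
#' 18 covered species, the combined partitioned matrix, and
#' posterior-like NNI-perturbed tree samples for the all-taxa and
#' shared-taxa selections.  Byte-identical output for a given
#' (config, seed).
#'
#' @param config a [study_config] (default).
#' @param seed RNG seed.
#' @return list with `tree`, `genus_tree`, `morph` (species-level),
#'   `mol`, `combined`, `samples` (list of [tree_sample]), `config`.
#' @export
make_study_like_dataset <- function(config = study_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(config$coverage %in% config$species))
    stop_domain("coverage subset is not contained in the species set")
  sd <- function(k) as.integer(seed) * 101L + k   # derived sub-seeds

  n_in <- length(config$species) - 4L
  out_tree <- simulate_tree(4L, seed = sd(1L),
                            labels = config$species[1:4])
  in_tree <- simulate_tree(n_in, seed = sd(2L),
                           labels = config$species[-(1:4)])
  tree <- parse_newick(paste0(
    "(", sub(";$", "", write_newick(out_tree)), ",",
    sub(";$", "", write_newick(in_tree)), ");"))

  # genus-level tree: one representative per genus
  drop_sp <- setdiff(config$species, c(config$genera, "rhynch_01a"))
  genus_tree <- prune_to_taxa(tree, setdiff(tree$tip.label, drop_sp))
  genus_tree$tip.label[genus_tree$tip.label == "rhynch_01a"] <- "rhynch_01"
  genus_tree <- canonicalize_tree(genus_tree)

  k_states <- with_seed(sd(3L), sample(as.integer(names(config$morph_state_probs)),
                                       config$n_morph_chars, replace = TRUE,
                                       prob = config$morph_state_probs))
  morph_genus <- simulate_mk_matrix(genus_tree, config$n_morph_chars,
                                    n_states = k_states,
                                    expected_changes = config$morph_expected_changes,
                                    seed = sd(4L),
                                    condition_informative = TRUE)
  morph_genus <- apply_missingness(morph_genus,
                                   data.frame(taxon = names(config$morph_missing),
                                              partition = "morphology",
                                              fraction = config$morph_missing),
                                   seed = sd(5L))
  morph <- expand_genus_to_species(morph_genus, config$species_map)

  mol_tree <- prune_to_taxa(tree, config$coverage)
  mol <- simulate_mk_matrix(mol_tree, config$n_mol_sites, n_states = 4,
                            expected_changes = config$mol_expected_changes,
                            seed = sd(6L), condition_informative = FALSE,
                            alphabet = DNA_ALPHABET, partition = "molecular")
  mol <- apply_missingness(mol,
                           data.frame(taxon = names(config$mol_missing),
                                      partition = "molecular",
                                      fraction = config$mol_missing),
                           seed = sd(7L))

  combined <- combine_partitions(morph, mol)
  samples <- list(
    all_taxa = perturb_tree_sample(tree, config$sample_size, config$n_nni,
                                   seed = sd(8L)),
    shared_taxa = perturb_tree_sample(mol_tree, config$sample_size,
                                      config$n_nni, seed = sd(9L)))
  list(tree = tree, genus_tree = genus_tree, morph = morph, mol = mol,
       combined = combined, samples = samples, config = config)
}
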