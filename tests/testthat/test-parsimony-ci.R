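test_that("parsimony length matches hand-traced cases", {
  tr <- parse_newick("((A,C),(B,D));")
  expect_identical(parsimony_length(tr, c(A = "0", B = "0", C = "1", D = "1")), 2L)
  # perfect binary character on its generating tree
  tr2 <- parse_newick("(((A,B),C),(D,E));")
  expect_identical(parsimony_length(tr2, c(A = "1", B = "1", C = "0",
                                           D = "0", E = "0")), 1L)
  # <= 1 non-missing taxon -> no changes possible
  expect_identical(parsimony_length(tr2, c(A = "1", B = "?", C = "?",
                                           D = "?", E = "?")), 0L)
  expect_identical(parsimony_length(tr2, c(A = "?", B = "?", C = "?",
                                           D = "?", E = "?")), 0L)
})

test_that("Hartigan equals exhaustive assignment minimization (oracle)", {
  set.seed(20)
  for (case in 1:30) {
    n <- sample(4:6, 1)
    tr <- random_resolved_tree(n, seed = 5000 + case)
    # random polytomies: collapse a random internal clade half the time
    if (case %% 2 == 0 && length(nontrivial_clades(tr)) > 1) {
      cl <- nontrivial_clades(tr)
      drop <- sample(length(cl), 1)
      tr <- treecontrast:::.build_from_clades(sort(tr$tip.label), cl[-drop],
                                              rep(1, length(cl) - 1))
    }
    k <- sample(2:3, 1)
    states <- sample(c(as.character(0:(k - 1)), "?"), n, replace = TRUE)
    names(states) <- tr$tip.label
    expect_identical(parsimony_length(tr, states),
                     oracle_parsimony(tr, states),
                     info = paste("case", case))
  }
})

test_that("Hartigan agrees with phangorn on resolved trees (second oracle)", {
  skip_if_not_installed("phangorn")
  for (seed in 1:10) {
    tr <- random_resolved_tree(8, seed)
    states <- sample(c("0", "1", "2"), 8, replace = TRUE)
    names(states) <- tr$tip.label
    pd <- phangorn::phyDat(matrix(states, ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("0", "1", "2"))
    expect_equal(parsimony_length(tr, states),
                 as.integer(phangorn::parsimony(ape::unroot(tr), pd,
                                                method = "fitch")))
  }
})

test_that("length is invariant to rerooting for unordered characters", {
  for (seed in 1:6) {
    tr <- random_resolved_tree(9, seed + 60)
    states <- setNames(sample(c("0", "1", "2", "?"), 9, replace = TRUE),
                       tr$tip.label)
    base <- parsimony_length(tr, states)
    for (og in sample(tr$tip.label, 3))
      expect_identical(
        parsimony_length(ape::root(ape::unroot(tr), outgroup = og,
                                   resolve.root = TRUE), states),
        base)
  }
})

test_that("adding missing data never increases steps (property)", {
  set.seed(77)
  for (rep in 1:10) {
    tr <- random_resolved_tree(10, seed = 700 + rep)
    states <- setNames(sample(c("0", "1"), 10, replace = TRUE), tr$tip.label)
    s0 <- parsimony_length(tr, states)
    states[sample(10, 3)] <- "?"
    expect_lte(parsimony_length(tr, states), s0)
  }
})

test_that("consistency index and report behave per definition", {
  tr <- parse_newick("((A,C),(B,D));")
  expect_equal(consistency_index(tr, c(A = "0", B = "0", C = "1", D = "1")), 0.5)
  tr2 <- parse_newick("(((A,B),C),(D,E));")
  expect_equal(consistency_index(tr2, c(A = "1", B = "1", C = "0",
                                        D = "0", E = "0")), 1)
  expect_true(is.na(consistency_index(tr2, c(A = "0", B = "0", C = "0",
                                             D = "0", E = "0"))))

  cells <- rbind(A = c("0", "0", "0"), B = c("0", "0", "1"),
                 C = c("1", "1", "0"), D = c("1", "1", "0"),
                 E = c("0", "1", "0"))
  x <- char_matrix(cells)
  rep_all <- ci_report(tr2, x)
  expect_identical(rep_all$id, 1:3)
  expect_true(all(rep_all$m <= rep_all$s))
  expect_true(all(rep_all$ci[!is.na(rep_all$ci)] > 0 &
                  rep_all$ci[!is.na(rep_all$ci)] <= 1))
  expect_equal(attr(rep_all, "ensemble_ci"),
               sum(rep_all$m[rep_all$in_ensemble]) /
                 sum(rep_all$s[rep_all$in_ensemble]))
  expect_lte(attr(rep_all, "ensemble_ci"), 1)
  # exclusion flag removes columns from the ensemble but not the table
  rep_ex <- ci_report(tr2, x, exclude_ids = 2L)
  expect_identical(nrow(rep_ex), 3L)
  expect_false(rep_ex$in_ensemble[2])
  # autapomorphies are flagged uninformative with ci 1
  aut <- char_matrix(rbind(A = "1", B = "0", C = "0", D = "0", E = "0"))
  rep_aut <- ci_report(tr2, aut)
  expect_equal(rep_aut$ci, 1)
  expect_false(rep_aut$informative)
})

test_that("columns entirely missing on the tree yield s = 0 and are excluded", {
  tr <- parse_newick("((A,B),(C,D));")
  cells <- rbind(A = c("0", "?"), B = c("1", "?"), C = c("0", "?"),
                 D = c("1", "?"))
  rep1 <- ci_report(tr, char_matrix(cells))
  expect_identical(rep1$s[2], 0L)
  expect_false(rep1$in_ensemble[2])
  expect_error(ci_report(tr, char_matrix(cells), ids = 2L), "s > 0")
})

test_that("exhaustive search enumerates (2n-3)!! trees and finds optima", {
  expect_length(treecontrast:::.enumerate_rooted(as.list(letters[1:5])), 105)

  # perfect characters of a 5-tip tree: the generating topology is optimal
  # and every optimum contains its clades
  gen <- parse_newick("((a,b),(c,(d,e)));")
  plan <- plan_allocation(gen, 3, seed = 1)
  m <- generate_perfect_matrix(gen, plan)
  res <- exhaustive_mp_search(m)
  gen_key <- write_newick(gen)
  opt_keys <- vapply(res$trees, write_newick, "")
  expect_true(gen_key %in% opt_keys)
  expect_identical(res$best_length, ncol(m$cells))
  # split-level recovery: optima are rootings of the generating unrooted tree
  for (tr in res$trees)
    for (cl in plan$clades) expect_true(split_in_tree(tr, cl))

  # single informative character: all trees with the implied clade optimal
  m1 <- char_matrix(matrix(c("1", "1", "0", "0", "0"), 5, 1,
                           dimnames = list(letters[1:5], NULL)))
  res1 <- exhaustive_mp_search(m1)
  expect_identical(res1$best_length, 1L)
  # every enumerated tree containing the implied clade is among the optima
  opt1 <- vapply(res1$trees, write_newick, "")
  all_trees <- treecontrast:::.enumerate_rooted(as.list(letters[1:5]))
  for (nt in all_trees) {
    phy <- parse_newick(treecontrast:::.nested_to_newick(nt))
    if (any(vapply(nontrivial_clades(phy), identical, TRUE, y = c("a", "b"))))
      expect_true(write_newick(phy) %in% opt1)
  }

  expect_error(exhaustive_mp_search(m, max_tips = 4), "exceeds")
})
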