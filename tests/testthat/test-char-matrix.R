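simple_nexus <- function(interleave = FALSE) {
  if (!interleave)
    paste0("#NEXUS\nBEGIN DATA;\n  DIMENSIONS NTAX=3 NCHAR=4;\n",
           "  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"0 1 2\";\n",
           "  MATRIX\n  taxA 01?2\n  taxB 0-12\n  taxC 0112\n  ;\nEND;\n")
  else
    paste0("#NEXUS\nBEGIN DATA;\n  DIMENSIONS NTAX=3 NCHAR=4;\n",
           "  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"0 1 2\"",
           " INTERLEAVE;\n  MATRIX\n  taxA 01\n  taxB 0-\n  taxC 01\n\n",
           "  taxA ?2\n  taxB 12\n  taxC 12\n  ;\nEND;\n")
}

test_that("read_nexus_matrix parses cells, MISSING and INAPPLICABLE", {
  x <- read_nexus_matrix(text = simple_nexus())
  expect_equal(dim(x), c(3L, 4L))
  expect_identical(rownames(x$cells), c("taxA", "taxB", "taxC"))
  expect_identical(unname(x$cells["taxA", 3]), "?")
  expect_identical(unname(x$cells["taxB", 2]), "-")
  expect_identical(x$alphabets$morphology, c("0", "1", "2"))
})

test_that("interleaved blocks reassemble to the sequential equivalent", {
  a <- read_nexus_matrix(text = simple_nexus(FALSE))
  b <- read_nexus_matrix(text = simple_nexus(TRUE))
  expect_identical(a$cells, b$cells)
})

test_that("parser rejects ragged and inconsistent matrices", {
  bad <- sub("taxB 0-12", "taxB 0-1", simple_nexus())
  expect_error(read_nexus_matrix(text = bad), "ragged")
  bad2 <- sub("NTAX=3", "NTAX=4", simple_nexus())
  expect_error(read_nexus_matrix(text = bad2), "declares")
  expect_error(read_nexus_matrix(text = "#NEXUS\nBEGIN TAXA;\nEND;\n"),
               "no DATA")
})

test_that("read-write-read round-trips cells, taxa order and partitions", {
  ds <- make_study_like_dataset(seed = 5)
  doc <- write_nexus_matrix(ds$combined)
  back <- read_nexus_matrix(text = doc)
  expect_identical(back$cells, ds$combined$cells)
  expect_identical(back$partition, ds$combined$partition)
  expect_identical(rownames(back$cells), rownames(ds$combined$cells))
})

test_that("informativeness follows the two-states-twice criterion", {
  expect_true(is_parsimony_informative(c("0", "0", "1", "1")))
  expect_false(is_parsimony_informative(c("0", "1", "1", "1")))
  expect_false(is_parsimony_informative(c("0", "0", "1", "?")))
  expect_false(is_parsimony_informative(c("0", "0", "1", "2")))
  expect_true(is_parsimony_informative(c("0", "0", "1", "1", "2", "2")))
  expect_false(is_parsimony_informative(c("0", "0", "0", "0")))
  # inapplicable treated as missing
  expect_false(is_parsimony_informative(c("0", "0", "1", "-")))
})

test_that("informativeness <=> tree length varies across topologies (oracle)", {
  # brute force: a column is informative iff its exhaustive-search optimum
  # differs from its worst fully resolved tree length
  cols <- list(c("0", "0", "1", "1", "2"), c("0", "0", "1", "2", "2"),
               c("0", "1", "1", "1", "1"), c("0", "0", "1", "2", "1"),
               c("0", "1", "2", "2", "?"))
  taxa <- paste0("t", 1:5)
  for (col in cols) {
    m <- char_matrix(matrix(col, 5, 1, dimnames = list(taxa, NULL)))
    trees <- treecontrast:::.enumerate_rooted(as.list(taxa))
    lens <- vapply(trees, function(tr) {
      phy <- parse_newick(treecontrast:::.nested_to_newick(tr))
      parsimony_length(phy, setNames(col, taxa))
    }, integer(1))
    expect_identical(is_parsimony_informative(col),
                     min(lens) != max(lens))
  }
})

test_that("filter_informative keeps ids stable and is idempotent", {
  cells <- rbind(t1 = c("0", "0", "0", "0"),
                 t2 = c("0", "1", "0", "1"),
                 t3 = c("1", "1", "0", "1"),
                 t4 = c("1", "0", "0", "?"))
  x <- char_matrix(cells)
  res <- filter_informative(x)
  expect_identical(res$dropped, c(3L, 4L))
  expect_identical(res$matrix$col_id, c(1L, 2L))
  again <- filter_informative(res$matrix)
  expect_length(again$dropped, 0)
  expect_identical(again$matrix$cells, res$matrix$cells)

  # all-invariant matrix drops everything
  inv <- char_matrix(matrix("0", 3, 2, dimnames = list(paste0("s", 1:3), NULL)))
  expect_identical(filter_informative(inv)$dropped, c(1L, 2L))
})

test_that("taxon subsetting can render further columns uninformative", {
  cells <- rbind(a = c("0", "0"), b = c("0", "1"), c = c("1", "1"),
                 d = c("1", "0"), e = c("0", "1"))
  x <- char_matrix(cells)
  expect_length(filter_informative(x)$dropped, 0)
  sub <- subset_matrix(x, taxa = c("a", "b", "c"))
  expect_gt(length(filter_informative(sub)$dropped), 0)
})

test_that("missing percentages match hand counts and survive replication", {
  x <- read_nexus_matrix(text = simple_nexus())
  mp <- missing_percentages(x)
  expect_equal(mp$morphology, c(25, 25, 0))
  # 45 of 66 missing -> 68.2 after 1-decimal rounding
  cells <- matrix("0", 2, 66, dimnames = list(c("full", "sparse"), NULL))
  cells["sparse", 1:45] <- "?"
  m66 <- char_matrix(cells)
  expect_equal(round(missing_percentages(m66)$morphology, 1), c(0, 68.2))
  # all-missing row
  cells["sparse", ] <- "?"
  expect_equal(missing_percentages(char_matrix(cells))$morphology[2], 100)
  # inapplicable counted only when requested
  expect_equal(missing_percentages(x, treat_inapplicable_as_missing = FALSE)$morphology,
               c(25, 0, 0))
  # replication leaves percentages unchanged
  rep5 <- replicate_columns(m66, 5)
  expect_equal(missing_percentages(rep5)$morphology,
               missing_percentages(m66)$morphology)
})

test_that("replicate_columns multiplies columns contiguously", {
  ds <- make_study_like_dataset(seed = 3)
  m54 <- subset_matrix(ds$morph, ids = 1:54)
  big <- replicate_columns(m54, 53)
  expect_equal(ncol(big$cells), 2862)
  expect_identical(big$cells[, 1:53],
                   matrix(rep(m54$cells[, 1], 53), ncol = 53,
                          dimnames = list(rownames(m54$cells), NULL)))
  expect_identical(replicate_columns(m54, 1)$cells, m54$cells)
  expect_error(replicate_columns(m54, 0), "positive")
  # informativeness preserved per replicate
  keep <- filter_informative(m54)$matrix$col_id
  src <- attr(big, "source_id")
  expect_identical(sort(unique(src[filter_informative(big)$matrix$col_id])),
                   keep)
})

test_that("genus rows expand to identical species rows", {
  cells <- rbind(GenA = c("0", "1"), GenB = c("1", "?"))
  x <- char_matrix(cells)
  out <- expand_genus_to_species(x, list(GenA = c("GenA_sp1", "GenA_sp2")))
  expect_identical(rownames(out$cells), c("GenA_sp1", "GenA_sp2", "GenB"))
  expect_identical(out$cells["GenA_sp1", ], out$cells["GenA_sp2", ])
  expect_identical(out$cells["GenB", ], cells["GenB", ])
  expect_error(expand_genus_to_species(x, list(GenZ = "z1")), "absent")
  expect_error(expand_genus_to_species(x, list(GenA = character(0))), "empty")
})

test_that("combine_partitions unions taxa and fills MISSING", {
  morph <- char_matrix(rbind(a = c("0", "1"), b = c("1", "0"), c = c("0", "0")),
                       partition = "morphology")
  mol <- char_matrix(rbind(a = c("A", "C"), b = c("A", "G")),
                     partition = "molecular",
                     alphabets = list(molecular = c("A", "C", "G", "T")))
  comb <- combine_partitions(morph, mol)
  expect_equal(dim(comb), c(3L, 4L))
  expect_true(all(comb$cells["c", comb$partition == "molecular"] == "?"))
  expect_identical(comb$col_id, 1:4)
  # split recovers both inputs
  back <- split_by_partition(comb)
  expect_identical(back$morphology$cells, morph$cells)
  expect_identical(back$molecular$cells, mol$cells)
  expect_error(combine_partitions(morph, morph), "share partition")
})
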