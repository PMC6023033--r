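test_that("atomic signatures match the defining small cases", {
  m <- parse_smiles("C", "methane")
  expect_equal(atomic_signature(m, 1, 0)$canon, "[C]")
  # exhausted neighborhood degenerates to the lower-height string
  expect_equal(atomic_signature(m, 1, 2)$canon, "[C]")

  b <- parse_smiles("c1ccccc1", "benzene")
  h1 <- vapply(1:6, function(r) atomic_signature(b, r, 1)$canon, character(1))
  expect_equal(unique(h1), "[c](:[c]:[c])")

  e <- parse_smiles("CCO", "ethanol")
  central <- which(vapply(1:3, function(a)
    sum(e$structure$bonds$i == a | e$structure$bonds$j == a), integer(1)) == 2L)
  expect_equal(atomic_signature(e, central, 1)$canon, "[C]([C][O])")

  expect_error(atomic_signature(e, 9, 1), "invalid root")
})

test_that("molecular signature counts follow the per-height atom tally", {
  b <- parse_smiles("c1ccccc1", "benzene")
  ms <- molecular_signature(b, 0:2)
  expect_length(ms, 3L)
  expect_true(all(as.integer(ms) == 6L))

  e <- molecular_signature(parse_smiles("CCO", "eth"), 0)
  expect_equal(as.integer(e[c("0:[C]", "0:[O]")]), c(2L, 1L))

  for (nm in names(fixture_smiles)) {
    mol <- parse_smiles(fixture_smiles[[nm]], nm)
    n_heavy <- nrow(mol$structure$atoms)
    ms <- molecular_signature(mol, 0:2)
    h <- as.integer(sub(":.*", "", names(ms)))
    for (hh in 0:2)
      expect_equal(sum(as.integer(ms)[h == hh]), n_heavy, label = paste(nm, "h", hh))
  }
})

test_that("signatures are invariant under atom relabeling (100 permutations)", {
  mol <- parse_smiles("CC(=O)Oc1ccccc1C(=O)[O-]", "aspirin_anion")$structure
  ref <- sig_multiset(molecular_signature(mol))
  set.seed(42)
  for (k in 1:100) {
    pm <- permute_mol(mol, sample.int(nrow(mol$atoms)))
    expect_identical(sig_multiset(molecular_signature(pm)), ref)
  }
})

test_that("brute-force subtree oracle reproduces all fixture signatures", {
  for (nm in names(fixture_smiles)) {
    mol <- parse_smiles(fixture_smiles[[nm]], nm)$structure
    expect_lte(nrow(mol$atoms), 8L)
    expect_identical(sig_multiset(molecular_signature(mol, 0:3)),
                     oracle_molecular_signature(mol, 0:3),
                     label = nm)
  }
})

test_that("descriptor matrix columns, order, and occurrence windows are right", {
  lib <- sig_library(list(parse_smiles("C", "methane"),
                          parse_smiles("CC", "ethane")), "toy")
  dm <- build_matrix(lib, heights = 0:1)
  expect_equal(colnames(dm$counts), c("0:[C]", "1:[C]", "1:[C]([C])"))
  expect_equal(unname(dm$counts["methane", ]), c(1L, 1L, 0L))
  expect_equal(unname(dm$counts["ethane", ]), c(2L, 0L, 2L))
  expect_equal(unname(dm$col_min), c(1L, 1L, 2L))
  expect_equal(unname(dm$col_max), c(2L, 1L, 2L))
  expect_true(all(dm$col_min >= 1L))
  expect_true(all(colSums(dm$counts) > 0L))

  # degenerate lower-height strings can be merged on request
  dm2 <- build_matrix(lib, heights = 0:1, dedupe_degenerate_heights = TRUE)
  expect_equal(colnames(dm2$counts), c("0:[C]", "1:[C]([C])"))
  expect_equal(unname(dm2$counts["methane", ]), c(2L, 0L))

  # single compound: windows collapse to its own counts
  dm3 <- build_matrix(lib[1], heights = 0:1)
  expect_equal(dm3$col_min, dm3$col_max)

  # a duplicated structure leaves the windows unchanged
  rec <- lib$records[["ethane"]]; rec$id <- "ethane2"
  lib_dup <- sig_library(c(lib$records, list(rec)), "toy")
  dm4 <- build_matrix(lib_dup, heights = 0:1)
  expect_equal(unname(dm4$col_min), unname(dm$col_min))
  expect_equal(unname(dm4$col_max), unname(dm$col_max))

  expect_error(build_matrix(sig_library(list(), "empty")), "empty")
})

test_that("vocabulary grows monotonically and windows never narrow", {
  lib <- generate_library(planted_rule(), n = 20, active_fraction = 0.2, seed = 9)
  dm_small <- build_matrix(lib[1:12])
  extra <- generate_library(planted_rule(), n = 10, active_fraction = 0.2, seed = 10)
  extra_recs <- lapply(extra$records, function(r) { r$id <- paste0("X", r$id); r })
  lib_big <- sig_library(c(lib$records[1:12], extra_recs), "grown")
  dm_big <- build_matrix(lib_big)

  old_cols <- colnames(dm_small$counts)
  expect_true(all(old_cols %in% colnames(dm_big$counts)))
  expect_true(all(dm_big$col_min[old_cols] <= dm_small$col_min))
  expect_true(all(dm_big$col_max[old_cols] >= dm_small$col_max))
})
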