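test_that("overlap is 1 on training compounds, 0 on foreign ones, fractional in between", {
  sf <- shared_fit()
  dm <- build_matrix(sf$train)
  for (rec in sf$train$records[1:20])
    expect_equal(overlap(rec, dm), 1)

  # no shared signatures with an aromatic training vocabulary
  foreign <- parse_smiles("[Se]=[Se]", "foreign")
  expect_equal(overlap(foreign, dm), 0)

  # hand-built windows at height 0: candidate shares 3 of its 4 signatures
  train0 <- build_matrix(sig_library(list(parse_smiles("CCO", "t1"),
                                          parse_smiles("CCN", "t2")), "t"),
                         heights = 0)
  cand <- parse_smiles("NCC(O)Cl", "cand")
  expect_equal(overlap(cand, train0), 0.75)

  expect_error(overlap(structure(integer(0), heights = 0L, class = "sig_molsig"), train0),
               "empty")
})

test_that("round-1 strictness vs round-2 relaxation on a fractional overlap", {
  sf <- shared_fit()
  # candidate = training molecule plus a novel decoration: mostly in-vocabulary
  base_smiles <- sf$train$records[[1]]$smiles
  cand <- parse_smiles(paste0("CCCCCC", base_smiles), "decorated")
  om <- overlap(cand, sf$ens)
  expect_true(om > 0 && om < 1)

  v1 <- score_candidate(cand, sf$ens, round1_criteria())
  expect_true("overlap" %in% v1$failed_criteria)
  if (om >= 0.9) {
    v2 <- score_candidate(cand, sf$ens, round2_criteria())
    expect_false("overlap" %in% v2$failed_criteria)
  }
})

test_that("score floors are strict: a score exactly at the floor fails", {
  sf <- shared_fit()
  cand <- sf$train$records[[which(library_classes(sf$train) == "active")[1]]]
  v <- score_candidate(cand, sf$ens, permissive <- criteria_set(0, -Inf, TRUE, Inf))
  floor_at <- min(v$svmc_scores)
  at <- score_candidate(cand, sf$ens, criteria_set(0, floor_at, TRUE, Inf))
  expect_true("svmc_score" %in% at$failed_criteria)
  below <- score_candidate(cand, sf$ens,
                           criteria_set(0, floor_at - 1e-9, TRUE, Inf))
  expect_false("svmc_score" %in% below$failed_criteria)
})

test_that("planted-rule candidates pass and decoys fail", {
  sf <- shared_fit()
  cand <- generate_library(planted_rule(), n = 60, active_fraction = 0.2, seed = 11)
  res <- screen_library(cand, sf$ens, round2_criteria())
  truth <- attr(cand, "truth")
  expect_true(all(truth$active[res$verdicts$passed]))
  # every planted active whose signatures stay in-domain is recovered
  actives <- which(truth$active)
  in_domain <- vapply(cand$records[actives], function(r)
    overlap(r, sf$ens) >= 0.9, logical(1))
  expect_true(all(res$verdicts$passed[actives][in_domain]))
})

test_that("verdicts are chunk-invariant, deterministic, and wide open criteria pass all", {
  sf <- shared_fit()
  cand <- generate_library(planted_rule(), n = 30, active_fraction = 0.2, seed = 13)
  r1 <- screen_library(cand, sf$ens, round2_criteria(), chunk_size = 1)
  r2 <- screen_library(cand, sf$ens, round2_criteria(), chunk_size = 1000)
  expect_identical(r1$verdicts, r2$verdicts)
  r3 <- screen_library(cand, sf$ens, round2_criteria(), chunk_size = 1000)
  expect_identical(r2$verdicts, r3$verdicts)

  open_crit <- criteria_set(0, -Inf, TRUE, Inf)
  r_open <- screen_library(cand, sf$ens, open_crit)
  expect_equal(r_open$summary$passed, length(cand))

  expect_error(screen_library(cand, sf$ens, round2_criteria(), chunk_size = 0),
               "chunk_size")
})

test_that("file-based chunked screening matches in-memory screening", {
  sf <- shared_fit()
  cand <- generate_library(planted_rule(), n = 25, active_fraction = 0.2, seed = 17)
  smi <- tempfile(fileext = ".smi")
  write_library(cand, smi)
  r_mem <- screen_library(cand, sf$ens, round2_criteria())
  r_file <- screen_library(smi, sf$ens, round2_criteria(), chunk_size = 7)
  expect_equal(r_file$verdicts, r_mem$verdicts)
  expect_equal(r_file$summary$screened, 25L)
})

test_that("tightening any criterion never enlarges the passed set", {
  sf <- shared_fit()
  cand <- generate_library(planted_rule(), n = 40, active_fraction = 0.25, seed = 19)
  loose <- criteria_set(0, -Inf, TRUE, Inf)
  mid <- criteria_set(0.9, 0, TRUE, 50)
  tight <- criteria_set(1, 2, TRUE, 20)
  passed <- lapply(list(loose, mid, tight), function(cr)
    screen_library(cand, sf$ens, cr)$verdicts$passed)
  expect_true(all(passed[[2]] <= passed[[1]]))
  expect_true(all(passed[[3]] <= passed[[2]]))
})

test_that("overlap never decreases when the training set grows", {
  lib <- generate_library(planted_rule(), n = 30, active_fraction = 0.2, seed = 23)
  dm_small <- build_matrix(lib[1:15])
  dm_big <- build_matrix(lib)
  cand <- generate_library(planted_rule(), n = 15, active_fraction = 0.2, seed = 29)
  for (rec in cand$records)
    expect_gte(overlap(rec, dm_big), overlap(rec, dm_small))
})

test_that("a large screen recovers the planted actives with few impostors", {
  sf <- shared_fit()
  cand <- generate_library(planted_rule(), n = 1000, active_fraction = 0.05,
                           seed = 37)
  truth <- attr(cand, "truth")
  res <- screen_library(cand, sf$ens, round2_criteria(), chunk_size = 250)
  hits <- res$verdicts$passed
  n_planted <- sum(truth$active)
  expect_gte(n_planted, 40)
  expect_gte(sum(hits & truth$active), ceiling(0.9 * n_planted))
  expect_lte(sum(hits & !truth$active), 5)
})

test_that("hit_rate reproduces the validation-round arithmetic", {
  expect_equal(hit_rate(c(rep(TRUE, 4), rep(FALSE, 3))), 4 / 7, tolerance = 1e-12)
  expect_equal(hit_rate(c(rep(TRUE, 5), rep(FALSE, 5))), 0.5)
  expect_equal(hit_rate(rep(TRUE, 3)), 1)
  expect_error(hit_rate(logical(0)), "no tested")
})
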