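# Molecule filter, pair dataset assembly and train/test splitting.

test_that("filter rejects and accepts molecules per the ruleset", {
  expect_equal(apply_filter_rules("CC"),
               list(accepted = FALSE, rule = "min_bonds"))
  expect_equal(apply_filter_rules("CC(=O)[O-]")$rule,
               "forbid_charged_groups")
  expect_true(apply_filter_rules("CCCC")$accepted)
  expect_equal(apply_filter_rules("[2H]OC(C)C")$rule,
               "forbid_isotopes_D_T")
  expect_equal(apply_filter_rules("CCCC.Cl")$rule, "forbid_counter_ions")
  expect_equal(apply_filter_rules("CCCC[Si](C)(C)C")$rule,
               "allowed_elements")
  expect_equal(apply_filter_rules("CCC[CH3]")$rule, "implicit_hydrogens_only")
  expect_equal(apply_filter_rules(strrep("C", 45))$rule, "max_bonds")
  expect_error(apply_filter_rules("not-a-smiles"), "unparseable")
})

test_that("molecular weight bound is strict at 1500 Da", {
  # C17H26I10 sits just below 1500 Da; C18 with the same iodines is above
  under <- paste0(strrep("C(I)", 10), strrep("C", 7))
  over <- paste0(strrep("C(I)", 10), strrep("C", 8))
  mw <- mol_properties(c(under, over))$mol_weight
  expect_lt(mw[1], 1500)
  expect_gte(mw[2], 1500)
  expect_true(apply_filter_rules(under)$accepted)
  expect_equal(apply_filter_rules(over)$rule, "max_mol_weight")
})

test_that("filter is idempotent on accepted molecules", {
  corp <- fixture_corpus()
  flt <- filter_molecules(corp[1:25, ])
  expect_true(all(flt$accepted))
  again <- filter_molecules(flt)
  expect_true(all(again$accepted))
})

test_that("pair dataset drops overlong records and swaps sides cleanly", {
  corp <- fixture_corpus()[1:10, ]
  ds <- build_pair_dataset(corp, "selfies", "name")
  expect_s3_class(ds, "pair_dataset")
  expect_equal(nrow(ds$records), 10)
  expect_equal(ds$n_dropped, 0)

  # a name tokenizing to more than the target maximum must be dropped
  long_name <- paste(rep("2-methyl", 40), collapse = "-")
  corp2 <- corp
  corp2$name[1] <- long_name
  expect_gt(length(tokenize_iupac(long_name)$tokens), 78)
  ds2 <- build_pair_dataset(corp2, "selfies", "name")
  expect_equal(nrow(ds2$records), 9)
  expect_equal(ds2$n_dropped, 1)

  sw <- swap_sides(ds)
  expect_equal(sw$source_side, "name")
  expect_equal(nrow(sw$records), nrow(ds$records))
  expect_identical(sw$records$source_tokens, ds$records$target_tokens)

  expect_error(build_pair_dataset(corp[0, ], "selfies", "name"), "empty")
})

test_that("splitting is deterministic, covering and distribution-matched", {
  corp <- fixture_corpus()
  ds <- build_pair_dataset(corp, "selfies", "name")
  sp1 <- split_train_test(ds, 0.2, seed = 5)
  sp2 <- split_train_test(ds, 0.2, seed = 5)
  expect_identical(sp1$train$records$smiles, sp2$train$records$smiles)
  expect_identical(sp1$test$records$smiles, sp2$test$records$smiles)
  expect_equal(nrow(sp1$train$records) + nrow(sp1$test$records),
               nrow(ds$records))
  expect_length(intersect(sp1$train$records$smiles,
                          sp1$test$records$smiles), 0)
  test_tokens <- unique(unlist(sp1$test$records$source_tokens))
  expect_true(all(test_tokens %in% unlist(sp1$train$records$source_tokens)))
  expect_gte(sp1$cosine, 0.99)
  expect_error(split_train_test(ds, 0, seed = 1), "between 0 and 1")
  expect_error(split_train_test(ds, 1, seed = 1), "between 0 and 1")
})

test_that("token coverage holds across seeded corpora", {
  for (seed in 1:10) {
    corp <- fixture_corpus(60, seed = 100 + seed)
    ds <- build_pair_dataset(corp, "selfies", "name")
    sp <- split_train_test(ds, 0.15, seed = seed)
    test_tokens <- unique(unlist(sp$test$records$source_tokens))
    expect_true(all(test_tokens %in% unlist(sp$train$records$source_tokens)))
  }
})

test_that("pair files and drop logs round-trip through disk", {
  corp <- fixture_corpus()[1:8, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_file(corp, path)
  back <- read_pair_file(path)
  expect_equal(back$smiles, corp$smiles)
  expect_equal(back$name, corp$name)

  flt <- filter_molecules(tibble::tibble(smiles = c("CCCC", "CC")))
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_drop_log(flt, dpath)
  log <- utils::read.delim(dpath)
  expect_equal(log$smiles, "CC")
  expect_equal(log$violated_rule, "min_bonds")
})

test_that("SMILES files with identifiers are read", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCCC\tmol1", "CCO"), path)
  tbl <- read_molecules(path, "smiles")
  expect_equal(tbl$smiles, c("CCCC", "CCO"))
  expect_equal(tbl$id, c("mol1", NA))
})
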