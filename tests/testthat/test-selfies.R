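# SELFIES encoding/decoding: round trips and the robustness guarantee.

test_that("single-atom and two-atom encodings are canonical", {
  expect_equal(smiles_to_selfies("C"), "[C]")
  sf <- smiles_to_selfies("C=C")
  expect_equal(length(tokenize_selfies(sf)$tokens), 2)
  expect_equal(canonical_smiles(selfies_to_smiles(sf)),
               canonical_smiles("C=C"))
  expect_equal(selfies_to_smiles("[C]"), "C")
  expect_equal(canonical_smiles(selfies_to_smiles("[C][O]")),
               canonical_smiles("CO"))
})

test_that("round trip is canonically exact over the synthetic corpus", {
  corp <- fixture_corpus()
  for (i in seq_len(nrow(corp))) {
    expect_equal(selfies_to_smiles(corp$selfies[i]), corp$smiles[i])
  }
})

test_that("ring- and branch-containing structures survive the round trip", {
  cases <- c("C1CC1", "c1ccccc1O", "O=C(C=C)NC1(C(=O)N(C)C)CCCC1",
             "CC(C)(C)C", "N#CC=C", "C1CC2CCC1CC2")
  for (s in cases) {
    back <- selfies_to_smiles(smiles_to_selfies(s))
    expect_equal(canonical_smiles(back), canonical_smiles(s))
  }
})

test_that("structures outside the alphabet raise conversion errors", {
  expect_error(smiles_to_selfies("CC(=O)[O-]"), "alphabet")
  expect_error(smiles_to_selfies("[2H]OC(C)C"), "alphabet")
  expect_error(smiles_to_selfies("CC.[Na]"), "alphabet|disconnected")
})

test_that("malformed bracket structure raises a token error", {
  expect_error(tokenize_selfies("[C][O"), "malformed")
  expect_error(selfies_to_smiles("C"), "malformed")
})

test_that("random token strings always decode to valid structures", {
  corp <- fixture_corpus()
  alphabet <- unique(unlist(lapply(corp$selfies,
                                   function(s) tokenize_selfies(s)$tokens)))
  expect_gt(length(alphabet), 5)
  atom_tokens <- alphabet[grepl("^\\[[=#]?[A-Z][a-z]?\\]$", alphabet)]
  set.seed(4242)
  n_valid <- 0
  for (i in 1:1000) {
    # a molecular string needs at least one atom token; everything else
    # about the draw is unconstrained
    repeat {
      toks <- sample(alphabet, sample(3:20, 1), replace = TRUE)
      if (any(toks %in% atom_tokens)) break
    }
    smi <- selfies_to_smiles(paste(toks, collapse = ""))
    if (nzchar(smi) && !is.na(canonical_smiles(smi))) n_valid <- n_valid + 1
  }
  expect_equal(n_valid, 1000)
})

test_that("printed SELFIES strings split into their bracketed tokens", {
  toks <- tokenize_selfies(paste0(
    "[I][C][C][Branch1_2][Branch1_3][=C][N][C][Expl=Ring1][Branch1_1]",
    "[C][C]"))$tokens
  expect_length(toks, 12)
  expect_equal(toks[1], "[I]")
  expect_equal(toks[12], "[C]")
  expect_equal(detokenize(toks), paste0(
    "[I][C][C][Branch1_2][Branch1_3][=C][N][C][Expl=Ring1][Branch1_1]",
    "[C][C]"))
})
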