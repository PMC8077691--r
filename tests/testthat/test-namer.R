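# Nomenclature generator: naming, parsing and their inverse property.

test_that("standard names come out for simple molecules", {
  expect_equal(name_molecule("CCCC"), "butane")
  expect_equal(name_molecule("CC(C)C"), "2-methylpropane")
  expect_equal(name_molecule("CCO"), "ethanol")
  expect_equal(name_molecule("CC(=O)CC"), "butan-2-one")
  expect_equal(name_molecule("CC(O)C"), "propan-2-ol")
  expect_equal(name_molecule("CCN"), "ethanamine")
  expect_equal(name_molecule("OCCO"), "ethane-1,2-diol")
  expect_equal(name_molecule("CCCl"), "chloroethane")
})

test_that("chain selection follows longest-chain and lowest-locant rules", {
  # ethyl branch that extends into the parent chain
  expect_equal(name_molecule("CCC(CC)CC"), "3-ethylpentane")
  # numbering from the end nearest the principal group
  expect_equal(name_molecule("CCCCC(O)C"), "hexan-2-ol")
  # ties across the two numbering directions go to the prefix cited
  # first alphabetically (bromo before ethyl)
  expect_equal(name_molecule("CCC(CC)C(Br)CC"), "3-bromo-4-ethylhexane")
  # suffix priority: ketone over alcohol over amine
  expect_equal(name_molecule("CC(O)CC(=O)C"), "4-hydroxypentan-2-one")
  expect_equal(name_molecule("NCCO"), "2-aminoethan-1-ol")
})

test_that("out-of-family structures are refused", {
  expect_error(name_molecule("C1CCCCC1"), "acyclic")
  expect_error(name_molecule("CC(=O)OC"), "unsupported")
  expect_error(name_molecule("CC(=O)C(C)S"), "element")
  expect_error(name_molecule("CC=CC"), "unsupported")
  expect_error(name_molecule(strrep("C", 14)), "chain too long")
})

test_that("parser rebuilds structures and rejects bad names", {
  expect_equal(parse_name("butane"), canonical_smiles("CCCC"))
  expect_equal(parse_name("2-methylpropane"), canonical_smiles("CC(C)C"))
  expect_equal(parse_name("4-amino-2,2-dimethylpentan-3-one"),
               canonical_smiles("CC(N)C(=O)C(C)(C)C"))
  expect_error(parse_name("gibberish"), class = "chemnmt_invalid_name")
  expect_error(parse_name("pentan-1-one"), class = "chemnmt_invalid_name")
  expect_error(parse_name("2,3-dimethylethane"),
               class = "chemnmt_invalid_name")  # locants off the chain
  expect_error(parse_name("2-trimethylbutane"),
               class = "chemnmt_invalid_name")  # multiplier mismatch
  expect_error(parse_name("2,2,2-trimethylpropane"),
               class = "chemnmt_invalid_name")  # valence exceeded
})

test_that("substituent prefixes that embed chain stems parse correctly", {
  expect_equal(parse_name("3,7-diiododecan-5-one"),
               canonical_smiles("CCCC(I)CC(=O)CC(I)CC"))
  expect_equal(parse_name("4-iodododecane"),
               canonical_smiles(paste0("CCCC(I)", strrep("C", 8))))
})

test_that("namer and parser are inverse on seeded family members", {
  corp <- fixture_corpus(150, seed = 31)
  for (i in seq_len(nrow(corp))) {
    expect_equal(parse_name(corp$name[i]), corp$smiles[i])
    expect_equal(name_molecule(corp$smiles[i]), corp$name[i])
  }
})

test_that("generation is deterministic and exhausts gracefully", {
  spec <- family_spec(5, c("methyl"), 1, seed = 9)
  a <- generate_molecules(spec, 5)
  b <- generate_molecules(spec, 5)
  expect_identical(a, b)
  expect_length(generate_molecules(spec, 1), 1)
  # unsubstituted chains up to 4 carbons leave exactly one molecule with
  # at least 3 skeletal bonds: butane (ethane and propane fall short)
  tiny <- family_spec(4, character(0), 0, seed = 1)
  expect_identical(generate_molecules(tiny, 1), canonical_smiles("CCCC"))
  expect_error(generate_molecules(tiny, 2), "exhausted")
  # allowing a methyl adds the branched isomer
  branchy <- family_spec(3, "methyl", 1, seed = 1)
  expect_true(canonical_smiles("CC(C)C") %in%
                generate_molecules(branchy, 2))
})

test_that("every generated pair passes the filter and token limits", {
  corp <- fixture_corpus()
  flt <- filter_molecules(corp)
  expect_true(all(flt$accepted))
  expect_true(all(lengths(lapply(corp$name,
                                 function(x) tokenize_iupac(x)$tokens)) <= 78))
  expect_true(all(lengths(lapply(corp$selfies,
                                 function(x) tokenize_selfies(x)$tokens)) <= 48))
})

test_that("corrupting one name token yields invalid or different structures", {
  corp <- fixture_corpus()[1:40, ]
  set.seed(17)
  n_invalid <- 0; n_diff <- 0; n_same <- 0
  for (i in seq_len(nrow(corp))) {
    toks <- tokenize_iupac(corp$name[i])$tokens
    j <- sample(length(toks), 1)
    toks[j] <- sample(c("9", "oxo", "tri", "X", "-"), 1)
    corrupted <- detokenize(toks)
    if (corrupted == corp$name[i]) next
    res <- tryCatch(parse_name(corrupted), error = function(e) NA_character_)
    if (is.na(res)) n_invalid <- n_invalid + 1
    else if (res != corp$smiles[i]) n_diff <- n_diff + 1
    else n_same <- n_same + 1  # e.g. a locant swap across a symmetry
  }
  expect_gt(n_invalid, 0)
  # the vast majority of corruptions must be detectable
  expect_gte((n_invalid + n_diff) / (n_invalid + n_diff + n_same), 0.8)
})
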