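# Name tokenization, vocabularies and padded integer encoding.

test_that("names split on punctuation and after morphemes", {
  toks <- tokenize_iupac("1,3,7-trimethylpurine-2,6-dione")$tokens
  expect_equal(toks, c("1", ",", "3", ",", "7", "-", "tri", "methyl",
                       "purine", "-", "2", ",", "6", "-", "di", "one"))
  expect_equal(tokenize_iupac("butane")$tokens, "butane")
  expect_equal(tokenize_iupac("cyclohexane")$tokens[1], "cyclo")
  expect_error(tokenize_iupac(""), "empty")
})

test_that("longest-match-first resolves overlapping morphemes", {
  # "butane" beats "butan"; "ethene" beats "ethen"
  expect_equal(tokenize_iupac("butanepent")$tokens[1], "butane")
  expect_equal(tokenize_iupac("ethene")$tokens, "ethene")
  # morpheme ends its token: the residual before it stays attached
  expect_equal(tokenize_iupac("purinemethyl")$tokens, c("purinemethyl"))
})

test_that("detokenization inverts both tokenizers on generated names", {
  corp <- fixture_corpus()
  for (nm in corp$name) {
    toks <- tokenize_iupac(nm)
    expect_true(all(nzchar(toks$tokens)))
    expect_equal(detokenize(toks), nm)
  }
  for (sf in corp$selfies) {
    expect_equal(detokenize(tokenize_selfies(sf)), sf)
  }
  expect_equal(detokenize(character(0)), "")
  expect_equal(detokenize(c("tri", "methyl")), "trimethyl")
})

test_that("vocabulary applies the rare-token cutoff deterministically", {
  corpus <- list(rep("[C]", 5), "[O]")
  v <- build_vocabulary(corpus, min_count = 2)
  expect_equal(setdiff(v$index_to_token, c("<pad>", "<start>", "<end>")),
               "[C]")
  v1 <- build_vocabulary(corpus, min_count = 1)
  expect_setequal(setdiff(v1$index_to_token, c("<pad>", "<start>", "<end>")),
                  c("[C]", "[O]"))
  # identical rebuild
  v2 <- build_vocabulary(corpus, min_count = 1)
  expect_identical(v1$token_to_index, v2$token_to_index)
  expect_error(build_vocabulary(corpus, min_count = 10), "cutoff")
  expect_error(build_vocabulary(list()), "empty")
})

test_that("encoding pads to the exact layout and inverts", {
  v <- build_vocabulary(list(c("[C]", "[O]", "[N]")))
  enc <- encode_sequence("[C]", v, padded_length = 5)
  expect_length(enc, 5)
  expect_equal(enc[1], v$start)
  expect_equal(enc[3], v$end)
  expect_equal(enc[4:5], c(0L, 0L))
  expect_equal(decode_sequence(enc, v)$tokens, "[C]")

  expect_error(encode_sequence("[X]", v, 5), "out-of-vocabulary.*\\[X\\]")
  expect_error(encode_sequence(rep("[C]", 77), v, 78), "too long")

  set.seed(99)
  for (i in 1:200) {
    toks <- sample(c("[C]", "[O]", "[N]"), sample(1:8, 1), replace = TRUE)
    enc <- encode_sequence(toks, v, 12)
    expect_equal(decode_sequence(enc, v)$tokens, toks)
    # pad never precedes end
    pads <- which(enc == v$pad)
    if (length(pads) > 0) expect_true(min(pads) > match(v$end, enc))
  }
})

test_that("vocabularies survive JSON serialization", {
  corp <- fixture_corpus()
  v <- build_vocabulary(lapply(corp$name,
                               function(x) tokenize_iupac(x)$tokens))
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v, path)
  v2 <- read_vocabulary(path)
  expect_identical(v$index_to_token, v2$index_to_token)
  expect_identical(unname(v$token_to_index[v$index_to_token]),
                   unname(v2$token_to_index[v2$index_to_token]))
})

test_that("token files are written space-joined one sequence per line", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_token_file(list(c("tri", "methyl"), "[C]"), path)
  expect_equal(readLines(path), c("tri methyl", "[C]"))
})
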