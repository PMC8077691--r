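# Sentence BLEU: clipped precisions, brevity penalty, preset scores.

test_that("modified precision clips candidate n-gram counts", {
  expect_equal(as.numeric(modified_precision(c("a", "b"), c("a", "a", "a"), 1)),
               1 / 3)
  expect_equal(as.numeric(modified_precision(letters[1:5], letters[1:5], 3)),
               1)
  short <- modified_precision(letters[1:5], c("a"), 2)
  expect_equal(as.numeric(short), 0)
  expect_false(attr(short, "defined"))
})

test_that("brevity penalty follows its closed form", {
  expect_equal(brevity_penalty(16, 11), exp(1 - 16 / 11))
  expect_equal(brevity_penalty(5, 9), 1)
  expect_equal(brevity_penalty(5, 5), 1)
  expect_equal(brevity_penalty(5, 0), 0)
})

test_that("published worked examples reproduce to two decimals", {
  ref <- appendix_reference()
  rep_ww <- bleu_report(ref, tokenize_iupac("1,3,7-trimethylpurine-2,6-trione"))
  expect_equal(round(unname(rep_ww$scores), 2), c(0.94, 0.90, 0.90, 0.88))
  expect_equal(round(rep_ww$precisions[1], 2), 0.94)  # 15/16

  rep_wp <- bleu_report(ref, tokenize_iupac("1,3,7-trimethylpurine-2,6,trione"))
  expect_equal(round(unname(rep_wp$scores), 2), c(0.88, 0.84, 0.84, 0.81))

  rep_sh <- bleu_report(ref, tokenize_iupac("1,3,7-trimethylpurine-2"))
  expect_equal(round(unname(rep_sh$scores), 2), rep(0.63, 4))
  expect_equal(rep_sh$brevity_penalty, exp(1 - 16 / 11))

  rep_wo <- bleu_report(ref, tokenize_iupac("1,3,7-trimethylpurine-6,2-dione"))
  expect_equal(round(unname(rep_wo$scores), 2), c(1.00, 0.86, 0.80, 0.71))

  # over-long candidate (known printed-value discrepancy: the computed
  # unigram precision is 16/26)
  rep_lg <- bleu_report(ref, tokenize_iupac(
    "1,3,7-trimethylpurine-2,6-dione,6-dione,6-dione"))
  expect_equal(rep_lg$precisions[1], 16 / 26)
  expect_equal(rep_lg$brevity_penalty, 1)
})

test_that("identical sequences score 1 under every preset", {
  toks <- tokenize_iupac("4-amino-2,2-dimethylpentan-3-one")$tokens
  for (w in bleu_weight_presets()) {
    expect_equal(sentence_bleu(toks, toks, w), 1)
  }
})

test_that("unigram BLEU ignores order for equal-length candidates", {
  set.seed(7)
  for (i in 1:25) {
    toks <- sample(letters[1:6], 10, replace = TRUE)
    perm <- sample(toks)
    expect_equal(sentence_bleu(toks, perm, bleu_weight_presets()$bleu1),
                 1)
  }
})

test_that("zero weighted precision zeroes the score (no smoothing)", {
  expect_equal(sentence_bleu(c("a", "b", "c"), c("x", "y", "z")), 0)
  # bigram precision zero but unigram positive
  expect_equal(sentence_bleu(c("a", "b"), c("b", "a", "x"),
                             bleu_weight_presets()$bleu2), 0)
  expect_gt(sentence_bleu(c("a", "b"), c("b", "a", "x"),
                          bleu_weight_presets()$bleu1), 0)
})

test_that("agreement with the independent oracle on random pairs", {
  py <- python_bin()
  expect_true(nzchar(py))
  set.seed(123)
  n <- 500
  refs <- character(n); cands <- character(n)
  vocabs <- c("tri", "methyl", "1", "2", ",", "-", "one", "di", "purine")
  for (i in seq_len(n)) {
    refs[i] <- paste(sample(vocabs, sample(3:15, 1), replace = TRUE),
                     collapse = " ")
    cands[i] <- paste(sample(vocabs, sample(0:15, 1), replace = TRUE),
                      collapse = " ")
  }
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(refs, cands, sep = "\t"), tsv)
  oracle_script <- system.file("python", "bleu_oracle.py", package = "chemnmt")
  for (w in bleu_weight_presets()[c("bleu1", "bleu4")]) {
    out <- system2(py, c(oracle_script, tsv, as.character(w)),
                   stdout = TRUE)
    oracle <- as.numeric(out)
    mine <- vapply(seq_len(n), function(i) {
      sentence_bleu(strsplit(refs[i], " ")[[1]],
                    if (nzchar(cands[i])) strsplit(cands[i], " ")[[1]]
                    else character(0), w)
    }, numeric(1))
    expect_lt(max(abs(mine - oracle)), 1e-9)
  }
})
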