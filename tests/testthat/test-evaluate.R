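# Corpus evaluation: BLEU statistics, validity accounting, Tanimoto
# readjustment.

test_that("perfect predictions give a perfect report", {
  corp <- fixture_corpus()
  # 4-gram BLEU needs at least four tokens; unsubstituted parents like
  # "butane" tokenize to a single token and score 0 even when identical
  long_enough <- lengths(purrr::map(corp$name,
                                    ~ tokenize_iupac(.x)$tokens)) >= 4
  corp <- corp[long_enough, ][1:10, ]
  rep <- evaluate_translations(
    tibble::tibble(reference = corp$name, prediction = corp$name))
  g <- glance(rep)
  expect_equal(g$average_bleu, 1)
  expect_equal(g$frac_bleu_1, 100)
  expect_equal(g$valid_name_pct, 100)
  expect_equal(g$avg_tanimoto_total, 1)
  expect_equal(g$avg_tanimoto_valid, 1)
  expect_equal(g$tanimoto_1_total_pct, 100)
})

test_that("invalid predictions are counted and zero-scored in totals", {
  rep <- evaluate_translations(tibble::tibble(
    reference = c("butane", "pentan-2-ol"),
    prediction = c("butane", "not-a-name")))
  g <- glance(rep)
  expect_equal(g$valid_name_pct, 50)
  expect_equal(g$invalid_name_pct, 50)
  expect_equal(g$avg_tanimoto_valid, 1)     # the one valid pair is exact
  expect_equal(g$avg_tanimoto_total, 0.5)   # readjusted to both pairs
  expect_equal(g$valid_name_pct + g$invalid_name_pct, 100)
  expect_equal(g$avg_tanimoto_total,
               g$avg_tanimoto_valid * g$valid_name_pct / 100)
})

test_that("near-miss predictions score between 0 and 1", {
  rep <- evaluate_translations(tibble::tibble(
    reference = "4-amino-2,2-dimethylpentan-3-one",
    prediction = "5-amino-2,2-dimethylpentan-3-one"))
  td <- tidy(rep)
  expect_lt(td$bleu, 1)
  expect_gt(td$bleu, 0)
  expect_true(td$valid)
  expect_lt(td$tanimoto, 1)
  expect_gt(td$tanimoto, 0.5)
})

test_that("a NULL backend restricts the report to the BLEU block", {
  rep <- evaluate_translations(
    tibble::tibble(reference = "butane", prediction = "butane"),
    name_to_structure = NULL)
  g <- glance(rep)
  expect_true(g$bleu_block_only)
  expect_false("valid_name_pct" %in% names(g))
})

test_that("report objects tidy, glance, plot and serialize", {
  corp <- fixture_corpus()[1:6, ]
  pred <- c(corp$name[1:5], "broken")
  rep <- evaluate_translations(
    tibble::tibble(reference = corp$name, prediction = pred))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_true(all(c("p1", "p4", "bleu", "valid", "tanimoto") %in% names(td)))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  prefix <- file.path(withr::local_tempdir(), "report")
  write_eval_report(rep, prefix)
  expect_true(file.exists(paste0(prefix, ".json")))
  expect_true(file.exists(paste0(prefix, ".txt")))
  expect_true(file.exists(paste0(prefix, "_pairs.tsv")))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$n_pairs, 6)
})
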