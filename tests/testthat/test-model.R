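# Attention, masked loss, training behavior and greedy decoding.

test_that("attention normalizes and reduces correctly", {
  set.seed(5)
  h <- 8
  params <- list(W1 = matrix(rnorm(h * h), h), W2 = matrix(rnorm(h * h), h),
                 v = rnorm(h))
  # single source position: weight 1, context = that output
  enc1 <- matrix(rnorm(h), 1)
  a1 <- attend(rnorm(h), enc1, params)
  expect_equal(a1$weights, 1)
  expect_equal(a1$context, as.numeric(enc1))
  # identical encoder outputs: uniform weights
  encu <- matrix(rep(rnorm(h), 5), 5, byrow = TRUE)
  au <- attend(rnorm(h), encu, params)
  expect_equal(au$weights, rep(1 / 5, 5))
  # brute-force softmax recomputation
  enc <- matrix(rnorm(6 * h), 6)
  q <- rnorm(h)
  a <- attend(q, enc, params)
  scores <- vapply(1:6, function(t) {
    sum(params$v * tanh(as.numeric(enc[t, ] %*% params$W1) +
                          as.numeric(q %*% params$W2)))
  }, numeric(1))
  w <- exp(scores) / sum(exp(scores))
  expect_equal(a$weights, w, tolerance = 1e-6)
  expect_equal(a$context, as.numeric(crossprod(enc, w)), tolerance = 1e-6)
  expect_equal(sum(a$weights), 1, tolerance = 1e-6)
  expect_true(all(a$weights >= 0))
  # invariance to constant score shifts is inherent to softmax; check a
  # dimension mismatch errors
  expect_error(attend(rnorm(3), enc, params), "dimension mismatch")
})

test_that("masked loss ignores pad positions", {
  onehot <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0))
  expect_equal(masked_loss(c(1L, 2L), onehot), 0)
  expect_warning(l <- masked_loss(c(0L, 0L), onehot), "all-pad")
  expect_equal(l, 0)
  V <- 7
  unif <- matrix(1 / V, 4, V)
  expect_equal(masked_loss(c(1L, 3L, 0L, 2L), unif), log(V))
})

test_that("training reduces the loss and is seed-deterministic", {
  corp <- fixture_corpus()
  ds <- build_pair_dataset(corp, "selfies", "name")
  cfg <- model_config(embedding_dim = 16, recurrent_units = 24,
                      learning_rate = 5e-3, batch_size = 32,
                      epochs = 5, seed = 7)
  m1 <- train_translator(ds, cfg)
  expect_length(m1$loss_trace, 5)
  expect_lt(m1$loss_trace[5], m1$loss_trace[1])
  m2 <- train_translator(ds, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_error(
    train_translator(
      structure(list(records = corp[0, ]), class = "pair_dataset"), cfg),
    "empty")
})

test_that("greedy decoding respects the length bound and end token", {
  corp <- fixture_corpus()
  ds <- build_pair_dataset(corp, "selfies", "name")
  cfg <- model_config(embedding_dim = 16, recurrent_units = 24,
                      learning_rate = 5e-3, batch_size = 32,
                      max_target_len = 12, epochs = 2, seed = 1)
  m <- train_translator(ds, cfg)
  for (i in 1:10) {
    out <- greedy_translate(m, tokenize_selfies(corp$selfies[i]))
    expect_lte(length(out$tokens), 12)
    expect_false(any(out$tokens %in% c("<start>", "<end>", "<pad>")))
  }
  # rigged output projection that always emits the end marker
  m2 <- m
  m2$params$out_W[] <- 0
  m2$params$out_b[] <- 0
  m2$params$out_b[m2$tgt_vocab$end + 1L] <- 100
  out <- greedy_translate(m2, tokenize_selfies(corp$selfies[1]))
  expect_length(out$tokens, 0)
})

test_that("save/load reproduces greedy translations bit-identically", {
  corp <- fixture_corpus()
  ds <- build_pair_dataset(corp, "selfies", "name")
  cfg <- model_config(embedding_dim = 16, recurrent_units = 24,
                      learning_rate = 5e-3, batch_size = 32,
                      epochs = 3, seed = 2)
  m <- train_translator(ds, cfg)
  dir <- withr::local_tempdir()
  save_translator(m, dir)
  m2 <- load_translator(dir)
  for (i in 1:8) {
    src <- tokenize_selfies(corp$selfies[i])
    expect_identical(greedy_translate(m, src)$tokens,
                     greedy_translate(m2, src)$tokens)
  }
})

test_that("the same architecture trains in both directions", {
  corp <- fixture_corpus()
  fwd <- build_pair_dataset(corp, "selfies", "name")
  rev <- swap_sides(fwd)
  cfg <- model_config(embedding_dim = 16, recurrent_units = 24,
                      learning_rate = 5e-3, batch_size = 32,
                      epochs = 3, seed = 7)
  m_fwd <- train_translator(fwd, cfg)
  m_rev <- train_translator(rev, cfg)
  expect_lt(tail(m_fwd$loss_trace, 1), m_fwd$loss_trace[1])
  expect_lt(tail(m_rev$loss_trace, 1), m_rev$loss_trace[1])
  expect_equal(m_rev$config$source_vocab_size, m_fwd$config$target_vocab_size)
})
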