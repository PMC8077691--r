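# Shared fixtures, generated in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small mixed-substituent corpus reused across module tests.
fixture_corpus <- function(n = 120, seed = 11) {
  key <- sprintf("corpus_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    spec <- family_spec(
      max_chain_length = 8,
      substituents = c("methyl", "ethyl", "hydroxy", "amino", "chloro",
                       "bromo", "oxo"),
      max_substituents = 3, seed = seed
    )
    .fixture_env[[key]] <- generate_pair_corpus(spec, n)
  }
  .fixture_env[[key]]
}

# Appendix reference tokens (the worked BLEU examples' reference string).
appendix_reference <- function() {
  tokenize_iupac("1,3,7-trimethylpurine-2,6-dione")$tokens
}

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  p
}
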