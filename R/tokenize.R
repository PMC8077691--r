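# Tokenizers for SELFIES strings and systematic chemical names, the
# vocabulary, and padded integer encoding of token sequences.

#' Delimiter rules for chemical-name tokenization
#'
#' A name is cut (i) around every punctuation delimiter, which becomes a
#' standalone token, and (ii) after every occurrence of a nomenclature
#' morpheme, scanning left to right with longest-match-first. Residual
#' substrings between cuts are single tokens.
#'
#' @param punctuation standalone delimiter characters.
#' @param morphemes nomenclature substrings that end a token.
#' @return an `iupac_delimiter_rules` list (morphemes sorted longest-first).
#' @export
iupac_delimiter_rules <- function(
    punctuation = c("(", ")", "{", "}", "[", "]", "-", ".", ","),
    morphemes = c("mono", "di", "tri", "tetra", "penta", "hexa", "hepta",
                  "octa", "nona", "deca", "oxo", "methyl", "hydroxy",
                  "benzene", "oxy", "chloro", "cyclo", "amino", "bromo",
                  "hydro", "fluoro", "methane", "cyano", "amido", "ethene",
                  "phospho", "amide", "butane", "carbono", "sulfane",
                  "sulfino", "iodo", "ethane", "ethyne", "bi", "imino",
                  "nitro", "butan", "idene", "sulfo", "carbon", "propane",
                  "ethen", "acetaldehyde", "benzo", "oxa", "nitroso",
                  "hydra", "iso")) {
  morphemes <- unique(morphemes)
  morphemes <- morphemes[order(-nchar(morphemes), morphemes)]
  structure(list(punctuation = punctuation, morphemes = morphemes),
            class = "iupac_delimiter_rules")
}

.token_sequence <- function(tokens, has_start = FALSE, has_end = FALSE,
                            padded_length = NULL) {
  structure(list(tokens = tokens, has_start = has_start, has_end = has_end,
                 padded_length = padded_length),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence> %d tokens: %s\n", length(x$tokens),
              paste(utils::head(x$tokens, 12), collapse = " ")))
  invisible(x)
}

#' Tokenize a SELFIES string
#'
#' Splits at every closed square bracket; tokens are the bracketed units
#' in order, brackets retained, so concatenating the tokens reproduces
#' the input exactly.
#'
#' @param selfies a SELFIES string ("" gives an empty sequence).
#' @return a `token_sequence`.
#' @export
tokenize_selfies <- function(selfies) {
  stopifnot(is.character(selfies), length(selfies) == 1)
  .token_sequence(.parse_selfies_tokens(selfies))
}

#' Tokenize a systematic chemical name
#'
#' @param name a non-empty name string.
#' @param rules an [iupac_delimiter_rules()] object.
#' @return a `token_sequence`; no token is empty and concatenating the
#'   tokens reproduces the input.
#' @export
tokenize_iupac <- function(name, rules = iupac_delimiter_rules()) {
  stopifnot(is.character(name), length(name) == 1)
  if (!nzchar(name)) stop("cannot tokenize an empty name")
  chars <- strsplit(name, "", fixed = FALSE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  buf <- ""
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% rules$punctuation) {
      if (nzchar(buf)) { tokens <- c(tokens, buf); buf <- "" }
      tokens <- c(tokens, ch)
      i <- i + 1L
      next
    }
    matched <- NA_character_
    for (m in rules$morphemes) {
      lm <- nchar(m)
      if (i + lm - 1L <= n && substr(name, i, i + lm - 1L) == m) {
        matched <- m
        break
      }
    }
    if (!is.na(matched)) {
      # the morpheme ends the current token (cut after the morpheme)
      tokens <- c(tokens, paste0(buf, matched))
      buf <- ""
      i <- i + nchar(matched)
    } else {
      buf <- paste0(buf, ch)
      i <- i + 1L
    }
  }
  if (nzchar(buf)) tokens <- c(tokens, buf)
  .token_sequence(tokens)
}

#' Reassemble a token sequence into its string
#'
#' Inverse of both tokenizers: concatenates content tokens with no
#' separators (start/end/pad markers are ignored).
#'
#' @param seq a `token_sequence` or plain character vector of tokens.
#' @return the concatenated string.
#' @export
detokenize <- function(seq) {
  tokens <- if (inherits(seq, "token_sequence")) seq$tokens else seq
  tokens <- tokens[!tokens %in% c("<start>", "<end>", "<pad>")]
  paste(tokens, collapse = "")
}

# ---- vocabulary -----------------------------------------------------------

#' Build a token vocabulary from a corpus of token sequences
#'
#' Reserved entries are pad (index 0), start and end (indices 1 and 2);
#' content tokens with corpus count below `min_count` are excluded, the
#' rest are indexed from 3 by descending count (ties broken
#' lexicographically), which makes rebuilding deterministic.
#'
#' @param sequences list of `token_sequence`s or character vectors.
#' @param min_count rare-token cutoff (tokens seen fewer times are dropped).
#' @return a `vocabulary` object.
#' @export
build_vocabulary <- function(sequences, min_count = 1L) {
  if (length(sequences) == 0) stop("empty corpus")
  tokens <- unlist(lapply(sequences, function(s) {
    if (inherits(s, "token_sequence")) s$tokens else s
  }))
  counts <- table(tokens)
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) stop("all tokens fall below the count cutoff")
  ord <- order(-as.numeric(counts), names(counts))
  content <- names(counts)[ord]
  index_to_token <- c("<pad>", "<start>", "<end>", content)
  token_to_index <- stats::setNames(seq_along(index_to_token) - 1L,
                                    index_to_token)
  structure(list(token_to_index = token_to_index,
                 index_to_token = index_to_token,
                 pad = 0L, start = 1L, end = 2L,
                 min_count = as.integer(min_count)),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d content tokens (+3 reserved), min_count=%d\n",
              length(x$index_to_token) - 3L, x$min_count))
  invisible(x)
}

#' Number of indices (reserved + content) in a vocabulary
#' @param vocab a `vocabulary`.
#' @return integer size.
#' @export
vocab_size <- function(vocab) length(vocab$index_to_token)

#' Encode a token sequence as a padded integer vector
#'
#' Layout is `[start, content indices..., end, pad...]` with total length
#' exactly `padded_length`.
#'
#' @param seq a `token_sequence` or character vector of content tokens.
#' @param vocab a `vocabulary`.
#' @param padded_length total encoded length (must be at least content
#'   length + 2).
#' @return integer vector of length `padded_length`.
#' @export
encode_sequence <- function(seq, vocab, padded_length) {
  tokens <- if (inherits(seq, "token_sequence")) seq$tokens else seq
  idx <- vocab$token_to_index[tokens]
  if (anyNA(idx)) {
    bad <- tokens[is.na(idx)][1]
    stop("out-of-vocabulary token: ", bad, call. = FALSE)
  }
  if (length(tokens) + 2L > padded_length) {
    stop(sprintf("sequence too long: %d content tokens need %d > %d positions",
                 length(tokens), length(tokens) + 2L, padded_length),
         call. = FALSE)
  }
  as.integer(c(vocab$start, idx, vocab$end,
               rep(vocab$pad, padded_length - length(tokens) - 2L)))
}

#' Decode an encoded integer vector back to its token sequence
#'
#' @param indices integer vector produced by [encode_sequence()].
#' @param vocab the `vocabulary` used for encoding.
#' @return a `token_sequence` of the content tokens.
#' @export
decode_sequence <- function(indices, vocab) {
  tokens <- vocab$index_to_token[indices + 1L]
  end_at <- match("<end>", tokens)
  if (!is.na(end_at)) tokens <- tokens[seq_len(end_at - 1L)]
  tokens <- tokens[!tokens %in% c("<start>", "<pad>")]
  .token_sequence(tokens)
}

#' Serialize a vocabulary to JSON
#'
#' @param vocab a `vocabulary`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(reserved = list(pad = 0L, start = 1L, end = 2L),
         min_count = vocab$min_count,
         token_to_index = as.list(vocab$token_to_index)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#'
#' @param path input file path.
#' @return a `vocabulary`.
#' @export
read_vocabulary <- function(path) {
  obj <- jsonlite::read_json(path)
  t2i <- unlist(obj$token_to_index)
  ord <- order(t2i)
  structure(list(token_to_index = t2i[ord],
                 index_to_token = names(t2i)[ord],
                 pad = 0L, start = 1L, end = 2L,
                 min_count = as.integer(obj$min_count)),
            class = "vocabulary")
}

#' Write tokenized sequences as space-joined lines
#'
#' One sequence per line, tokens separated by single spaces (the printed
#' corpus form).
#'
#' @param sequences list of `token_sequence`s or character vectors.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_token_file <- function(sequences, path) {
  lines <- vapply(sequences, function(s) {
    paste(if (inherits(s, "token_sequence")) s$tokens else s, collapse = " ")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
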