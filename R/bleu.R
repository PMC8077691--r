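# Sentence BLEU, implemented from the clipped n-gram precision and
# brevity penalty definitions (no smoothing: a zero weighted precision
# zeroes the score).

#' Preset BLEU weight schemes
#'
#' BLEU-1 (1,0,0,0), BLEU-2 (0.5,0.5,0,0), BLEU-3 (0.3,0.3,0.3,0) and
#' BLEU-4 (0.25,0.25,0.25,0.25). Weights need not sum to one: the score
#' uses `exp(sum(w_n * log(p_n)))` verbatim, which is what makes the
#' BLEU-3 preset (summing to 0.9) reproduce its published values.
#'
#' @return named list of numeric weight vectors.
#' @export
bleu_weight_presets <- function() {
  list(bleu1 = c(1, 0, 0, 0),
       bleu2 = c(0.5, 0.5, 0, 0),
       bleu3 = c(0.3, 0.3, 0.3, 0),
       bleu4 = c(0.25, 0.25, 0.25, 0.25))
}

# n-gram keys joined with a non-token separator so multi-character
# tokens cannot collide ("ab"+"c" vs "a"+"bc")
.ngrams <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(character(0))
  if (n == 1L) return(tokens)
  vapply(seq_len(L - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = "")
  }, character(1))
}

#' Modified (clipped) n-gram precision
#'
#' Counts candidate n-grams, clips each count at its reference count and
#' divides by the total candidate n-gram count. When the candidate is
#' shorter than `n` there are no candidate n-grams and the precision is
#' defined as 0 (flagged via the `defined` attribute).
#'
#' @param reference,candidate character vectors of tokens.
#' @param n n-gram order (>= 1).
#' @return precision in `[0,1]` with attribute `defined`.
#' @export
modified_precision <- function(reference, candidate, n) {
  stopifnot(n >= 1)
  cand <- .ngrams(candidate, n)
  if (length(cand) == 0) {
    return(structure(0, defined = FALSE))
  }
  ref <- .ngrams(reference, n)
  u <- unique(cand)
  cc <- tabulate(match(cand, u), length(u))
  rmatch <- match(ref, u)
  rc <- tabulate(rmatch[!is.na(rmatch)], length(u))
  structure(sum(pmin(cc, rc)) / length(cand), defined = TRUE)
}

#' Brevity penalty
#'
#' 1 when the candidate is at least as long as the reference, otherwise
#' `exp(1 - r/c)`; an empty candidate gets 0.
#'
#' @param reference_length,candidate_length token counts.
#' @return penalty in `(0, 1]` (0 for an empty candidate).
#' @export
brevity_penalty <- function(reference_length, candidate_length) {
  stopifnot(reference_length >= 0, candidate_length >= 0)
  if (candidate_length == 0) return(0)
  if (candidate_length >= reference_length) return(1)
  exp(1 - reference_length / candidate_length)
}

#' Sentence BLEU score
#'
#' `BP * exp(sum over n with w_n > 0 of w_n * log(p_n))`; if any
#' positively weighted precision is zero the score is zero (no
#' smoothing).
#'
#' @param reference,candidate character vectors of tokens (a
#'   `token_sequence` is also accepted).
#' @param weights numeric weight vector over n-gram orders (default the
#'   equal-weight 4-gram preset).
#' @return score in `[0,1]`.
#' @export
sentence_bleu <- function(reference, candidate,
                          weights = bleu_weight_presets()$bleu4) {
  if (inherits(reference, "token_sequence")) reference <- reference$tokens
  if (inherits(candidate, "token_sequence")) candidate <- candidate$tokens
  if (length(reference) == 0) stop("reference must be non-empty")
  if (all(weights <= 0)) stop("at least one weight must be positive")
  bp <- brevity_penalty(length(reference), length(candidate))
  if (bp == 0) return(0)
  acc <- 0
  for (n in seq_along(weights)) {
    if (weights[n] <= 0) next
    p <- as.numeric(modified_precision(reference, candidate, n))
    if (p == 0) return(0)
    acc <- acc + weights[n] * log(p)
  }
  bp * exp(acc)
}

#' Full BLEU report for one reference/candidate pair
#'
#' @param reference,candidate token vectors or `token_sequence`s.
#' @param max_n highest n-gram order reported.
#' @return a `bleu_report` list: `precisions` (p_1..p_max_n),
#'   `brevity_penalty`, `scores` (one per preset) and `headline`
#'   (the equal-weight 4-gram score).
#' @export
bleu_report <- function(reference, candidate, max_n = 4L) {
  if (inherits(reference, "token_sequence")) reference <- reference$tokens
  if (inherits(candidate, "token_sequence")) candidate <- candidate$tokens
  precisions <- vapply(seq_len(max_n), function(n) {
    as.numeric(modified_precision(reference, candidate, n))
  }, numeric(1))
  scores <- vapply(bleu_weight_presets(), function(w) {
    sentence_bleu(reference, candidate, w)
  }, numeric(1))
  structure(list(precisions = precisions,
                 brevity_penalty = brevity_penalty(length(reference),
                                                   length(candidate)),
                 scores = scores,
                 headline = scores[["bleu4"]]),
            class = "bleu_report")
}

#' @export
print.bleu_report <- function(x, ...) {
  cat(sprintf("<bleu_report> BLEU-4 %.2f | p = %s | BP %.4f\n",
              x$headline, paste(sprintf("%.3f", x$precisions), collapse = " "),
              x$brevity_penalty))
  invisible(x)
}
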