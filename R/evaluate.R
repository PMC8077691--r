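# Corpus-level evaluation protocol: BLEU statistics over all pairs,
# round-trip name validity through a pluggable name-to-structure
# backend, and fingerprint Tanimoto with readjustment of averages to
# the full test set (invalid predictions scored 0).

#' Evaluate predicted names against references
#'
#' For every (reference, prediction) pair: sentence BLEU under the four
#' preset weight schemes; then both names are sent through the
#' name-to-structure backend. Predictions the backend rejects count as
#' invalid. Tanimoto similarity (881-bit substructure keys) is computed
#' on the valid pairs; the "total" averages are readjusted to the full
#' number of pairs with invalid predictions contributing 0.
#'
#' @param data tibble with columns `reference` and `prediction`
#'   (name strings), or with `reference_tokens`/`prediction_tokens`
#'   list-columns for pre-tokenized input.
#' @param name_to_structure function mapping a name to a SMILES string,
#'   erroring on invalid names ([parse_name()] by default); `NULL`
#'   restricts the report to the BLEU block.
#' @param tokenizer function turning a string into a `token_sequence`
#'   ([tokenize_iupac()] by default; use [tokenize_selfies()] when
#'   evaluating SELFIES predictions).
#' @return an `eval_report`: list with `pairs` (per-pair tibble) and
#'   `summary` (one-row tibble; see [glance.eval_report()]).
#' @export
evaluate_translations <- function(data, name_to_structure = parse_name,
                                  tokenizer = tokenize_iupac) {
  stopifnot(all(c("reference", "prediction") %in% names(data)) ||
              all(c("reference_tokens", "prediction_tokens") %in% names(data)))
  n <- nrow(data)
  if (n == 0) stop("no pairs to evaluate")
  if (!"reference_tokens" %in% names(data)) {
    data <- dplyr::mutate(
      tibble::as_tibble(data),
      reference_tokens = purrr::map(.data$reference, ~ tokenizer(.x)$tokens),
      prediction_tokens = purrr::map(.data$prediction, function(p) {
        if (nzchar(p)) tokenizer(p)$tokens else character(0)
      })
    )
  }
  reports <- purrr::map2(data$reference_tokens, data$prediction_tokens,
                         bleu_report)
  pairs <- tibble::as_tibble(data)
  for (k in 1:4) {
    pairs[[paste0("p", k)]] <- purrr::map_dbl(reports, ~ .x$precisions[k])
    pairs[[paste0("bleu", k)]] <-
      purrr::map_dbl(reports, ~ .x$scores[[paste0("bleu", k)]])
  }
  pairs$brevity_penalty <- purrr::map_dbl(reports, "brevity_penalty")
  pairs$bleu <- purrr::map_dbl(reports, "headline")

  has_backend <- !is.null(name_to_structure)
  if (has_backend && "prediction" %in% names(pairs)) {
    conv <- function(x) {
      tryCatch(name_to_structure(x), error = function(e) NA_character_)
    }
    pairs$reference_smiles <- purrr::map_chr(pairs$reference, conv)
    pairs$prediction_smiles <- purrr::map_chr(pairs$prediction, conv)
    pairs$valid <- !is.na(pairs$prediction_smiles)
    pairs$tanimoto <- purrr::pmap_dbl(
      list(pairs$reference_smiles, pairs$prediction_smiles, pairs$valid),
      function(r, p, v) {
        if (!v || is.na(r)) return(NA_real_)
        tryCatch(tanimoto(pubchem_fingerprint(r), pubchem_fingerprint(p)),
                 error = function(e) NA_real_)
      })
  }

  summary <- tibble::tibble(
    n_pairs = n,
    average_bleu = mean(pairs$bleu),
    frac_bleu_1 = 100 * mean(pairs$bleu >= 1 - 1e-12),
    bleu1_mean = mean(pairs$bleu1), bleu2_mean = mean(pairs$bleu2),
    bleu3_mean = mean(pairs$bleu3), bleu4_mean = mean(pairs$bleu4)
  )
  if (has_backend && "valid" %in% names(pairs)) {
    tan <- ifelse(is.na(pairs$tanimoto), 0, pairs$tanimoto)
    n_valid <- sum(pairs$valid)
    summary$valid_name_pct <- 100 * n_valid / n
    summary$invalid_name_pct <- 100 - summary$valid_name_pct
    summary$tanimoto_1_total_pct <-
      100 * sum(pairs$valid & tan >= 1 - 1e-12) / n
    summary$tanimoto_1_valid_pct <-
      if (n_valid > 0) 100 * sum(pairs$valid & tan >= 1 - 1e-12) / n_valid
      else NA_real_
    summary$avg_tanimoto_total <- sum(tan) / n
    summary$avg_tanimoto_valid <-
      if (n_valid > 0) sum(tan[pairs$valid]) / n_valid else NA_real_
    summary$bleu_block_only <- FALSE
  } else {
    summary$bleu_block_only <- TRUE
  }
  structure(list(pairs = pairs, summary = summary), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<eval_report> %d pairs | avg BLEU %.2f | BLEU=1: %.2f%%\n",
              s$n_pairs, s$average_bleu, s$frac_bleu_1))
  if (!s$bleu_block_only) {
    cat(sprintf("  valid names %.2f%% | avg Tanimoto %.2f (total) %.2f (valid)\n",
                s$valid_name_pct, s$avg_tanimoto_total, s$avg_tanimoto_valid))
  }
  invisible(x)
}

#' Per-pair evaluation details
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return tibble with one row per pair: n-gram precisions, preset BLEU
#'   scores, brevity penalty, validity and Tanimoto columns.
#' @export
tidy.eval_report <- function(x, ...) {
  drop <- intersect(c("reference_tokens", "prediction_tokens"),
                    names(x$pairs))
  x$pairs[, setdiff(names(x$pairs), drop)]
}

#' One-row evaluation summary
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return one-row tibble with corpus-level BLEU, validity and Tanimoto
#'   statistics.
#' @export
glance.eval_report <- function(x, ...) x$summary

#' Write an evaluation report to disk
#'
#' JSON summary, aligned-column text summary and a tab-separated
#' per-pair detail file.
#'
#' @param report an `eval_report`.
#' @param path_prefix files are written as `<prefix>.json`,
#'   `<prefix>.txt` and `<prefix>_pairs.tsv`.
#' @return the prefix, invisibly.
#' @export
write_eval_report <- function(report, path_prefix) {
  jsonlite::write_json(as.list(report$summary),
                       paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  s <- report$summary
  txt <- utils::capture.output(print(as.data.frame(s), row.names = FALSE))
  writeLines(txt, paste0(path_prefix, ".txt"))
  utils::write.table(tidy(report), paste0(path_prefix, "_pairs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path_prefix)
}

#' Plot an evaluation report
#'
#' Histogram of per-pair BLEU scores, with Tanimoto overlaid when the
#' structure backend ran.
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  pairs <- object$pairs
  df <- tibble::tibble(metric = "BLEU", value = pairs$bleu)
  if ("tanimoto" %in% names(pairs)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      metric = "Tanimoto",
      value = ifelse(is.na(pairs$tanimoto), 0, pairs$tanimoto)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$metric)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.6,
                            bins = 20, boundary = 0) +
    ggplot2::labs(x = "score", y = "pairs",
                  title = "Per-pair translation quality") +
    ggplot2::theme_minimal()
}

#' Plot a training loss trace
#'
#' @param object a `translator_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.translator_model <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_trace),
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "masked cross-entropy",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Training summary of a translator
#'
#' @param x a `translator_model`.
#' @param ... unused.
#' @return one-row tibble with sizes and first/final loss.
#' @export
glance.translator_model <- function(x, ...) {
  tibble::tibble(
    source_vocab = x$config$source_vocab_size,
    target_vocab = x$config$target_vocab_size,
    embedding_dim = x$config$embedding_dim,
    recurrent_units = x$config$recurrent_units,
    epochs = length(x$loss_trace),
    first_loss = if (length(x$loss_trace)) x$loss_trace[1] else NA_real_,
    final_loss = if (length(x$loss_trace))
      utils::tail(x$loss_trace, 1) else NA_real_
  )
}

#' Per-epoch loss trace of a translator
#'
#' @param x a `translator_model`.
#' @param ... unused.
#' @return tibble with `epoch` and `loss`.
#' @export
tidy.translator_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}
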