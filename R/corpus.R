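# Corpus construction: the molecule filter ruleset, paired dataset
# assembly and token-balanced train/test splitting.

#' Molecule filter ruleset
#'
#' The default values reproduce the curation rules used to build the
#' translation corpora: molecular weight below 1500 Da, no counter ions
#' (multi-component SMILES), a restricted element set, no hydrogen
#' isotopes (D/T), between 3 and 40 heavy-atom bonds, no charged atoms,
#' and implicit hydrogens only.
#'
#' @param max_mol_weight upper bound (exclusive) on molecular weight, Da.
#' @param allowed_elements element whitelist (hydrogen is always allowed).
#' @param min_bonds,max_bonds inclusive bounds on heavy-atom bond count.
#' @param forbid_counter_ions reject multi-component structures.
#' @param forbid_isotopes_D_T reject deuterium/tritium.
#' @param forbid_charged_groups reject any atom with formal charge.
#' @param implicit_hydrogens_only reject explicitly written hydrogens.
#' @return a `filter_rules` list.
#' @export
filter_rules <- function(max_mol_weight = 1500,
                         allowed_elements = c("C", "H", "O", "N", "P", "S",
                                              "F", "Cl", "Br", "I", "Se", "B"),
                         min_bonds = 3L, max_bonds = 40L,
                         forbid_counter_ions = TRUE,
                         forbid_isotopes_D_T = TRUE,
                         forbid_charged_groups = TRUE,
                         implicit_hydrogens_only = TRUE) {
  stopifnot(min_bonds <= max_bonds)
  structure(list(max_mol_weight = max_mol_weight,
                 allowed_elements = allowed_elements,
                 min_bonds = as.integer(min_bonds),
                 max_bonds = as.integer(max_bonds),
                 forbid_counter_ions = forbid_counter_ions,
                 forbid_isotopes_D_T = forbid_isotopes_D_T,
                 forbid_charged_groups = forbid_charged_groups,
                 implicit_hydrogens_only = implicit_hydrogens_only),
            class = "filter_rules")
}

# Explicit hydrogen written as a bracket atom, e.g. [H], [CH3], [2H].
# Bracket atoms that need the bracket for charge are not counted
# (the "except in functional groups" reading).
.has_explicit_h <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  any(vapply(brackets, function(b) {
    grepl("H", b, fixed = TRUE) && !grepl("[+-]", b) && !grepl("nH", b)
  }, logical(1)))
}

#' Apply the molecule filter to one SMILES string
#'
#' Checks the rules in their canonical order and reports the first
#' violated rule, or acceptance if all rules pass. An unparseable SMILES
#' raises a parse error (distinct from a rejection).
#'
#' @param smiles a single SMILES string.
#' @param rules a [filter_rules()] object.
#' @return list with `accepted` flag and `rule` (first failing rule name
#'   or `NA` when accepted).
#' @export
apply_filter_rules <- function(smiles, rules = filter_rules()) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  g <- mol_graph(smiles)  # errors on unparseable input
  props <- mol_properties(smiles)
  fail <- function(rule) list(accepted = FALSE, rule = rule)

  if (!is.na(props$mol_weight) && props$mol_weight >= rules$max_mol_weight) {
    return(fail("max_mol_weight"))
  }
  if (rules$forbid_counter_ions && grepl(".", smiles, fixed = TRUE)) {
    return(fail("forbid_counter_ions"))
  }
  if (!all(g$atoms$element %in% c(rules$allowed_elements, "H"))) {
    return(fail("allowed_elements"))
  }
  if (rules$forbid_isotopes_D_T) {
    d_t <- grepl("\\[[23]H\\]|\\bD\\b|\\bT\\b", smiles) ||
      any(g$atoms$element == "H" & g$atoms$isotope %in% c(2L, 3L))
    if (d_t) return(fail("forbid_isotopes_D_T"))
  }
  nb <- nrow(g$bonds)
  if (nb < rules$min_bonds || nb > rules$max_bonds) {
    return(fail(if (nb < rules$min_bonds) "min_bonds" else "max_bonds"))
  }
  if (rules$forbid_charged_groups && any(g$atoms$charge != 0)) {
    return(fail("forbid_charged_groups"))
  }
  if (rules$implicit_hydrogens_only && .has_explicit_h(smiles)) {
    return(fail("implicit_hydrogens_only"))
  }
  list(accepted = TRUE, rule = NA_character_)
}

#' Filter a table of molecules
#'
#' Tibble-first wrapper around [apply_filter_rules()].
#'
#' @param data tibble (or data frame) with a `smiles` column.
#' @param rules a [filter_rules()] object.
#' @return the input tibble with logical `accepted` and character
#'   `violated_rule` columns appended; unparseable SMILES get
#'   `accepted = NA`.
#' @export
filter_molecules <- function(data, rules = filter_rules()) {
  stopifnot("smiles" %in% names(data))
  verdicts <- purrr::map(data$smiles, function(s) {
    tryCatch(apply_filter_rules(s, rules),
             error = function(e) list(accepted = NA, rule = "parse_error"))
  })
  data <- tibble::as_tibble(data)
  data$accepted <- purrr::map_lgl(verdicts, "accepted")
  data$violated_rule <- purrr::map_chr(verdicts, "rule")
  data
}

#' Read molecules from a SMILES text file or an SDF (V2000) file
#'
#' SMILES files carry one molecule per line with an optional
#' tab-separated identifier.
#'
#' @param path input file path.
#' @param format `"smiles"` or `"sdf"`.
#' @return tibble with columns `smiles` and `id`.
#' @export
read_molecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    tibble::tibble(
      smiles = vapply(parts, `[`, character(1), 1),
      id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                  character(1))
    )
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    smi <- vapply(seq_along(sdfset), function(i) {
      txt <- paste(c(unlist(ChemmineR::sdf2str(sdfset[[i]])), ""),
                   collapse = "\n")
      out <- ChemmineOB::convertFormat("SDF", "CAN", source = txt)
      sub("[\t\n ].*$", "", out)
    }, character(1))
    tibble::tibble(smiles = smi, id = ChemmineR::sdfid(sdfset))
  }
}

#' Assemble a paired translation dataset
#'
#' Tokenizes both sides of each record, drops records whose token count
#' exceeds the side's maximum, and records the translation direction.
#'
#' @param records tibble with columns `smiles`, `selfies`, `name`.
#' @param source_side,target_side `"selfies"` or `"name"`.
#' @param max_source_len,max_target_len maximum content token counts.
#' @return a `pair_dataset`: list with `records` (tibble including
#'   `source_tokens`/`target_tokens` list-columns), the two side labels,
#'   the maxima and `n_dropped`.
#' @export
build_pair_dataset <- function(records,
                               source_side = c("selfies", "name"),
                               target_side = c("name", "selfies"),
                               max_source_len = 48L, max_target_len = 78L) {
  source_side <- match.arg(source_side)
  target_side <- match.arg(target_side)
  if (source_side == target_side) stop("source and target side must differ")
  if (nrow(records) == 0) stop("empty input: no records to pair")
  stopifnot(all(c("selfies", "name") %in% names(records)))
  if (any(!nzchar(records$selfies)) || any(!nzchar(records$name))) {
    stop("every record must carry non-empty selfies and name strings")
  }
  tok <- function(side, x) {
    if (side == "selfies") tokenize_selfies(x)$tokens else
      tokenize_iupac(x)$tokens
  }
  records <- tibble::as_tibble(records)
  records$source_tokens <- purrr::map(records[[if (source_side == "selfies")
    "selfies" else "name"]], ~ tok(source_side, .x))
  records$target_tokens <- purrr::map(records[[if (target_side == "selfies")
    "selfies" else "name"]], ~ tok(target_side, .x))
  keep <- lengths(records$source_tokens) <= max_source_len &
    lengths(records$target_tokens) <= max_target_len
  structure(list(records = records[keep, ],
                 source_side = source_side, target_side = target_side,
                 max_source_len = as.integer(max_source_len),
                 max_target_len = as.integer(max_target_len),
                 n_dropped = sum(!keep)),
            class = "pair_dataset")
}

#' Swap the two sides of a pair dataset
#'
#' @param dataset a `pair_dataset`.
#' @return the dataset with source and target exchanged.
#' @export
swap_sides <- function(dataset) {
  stopifnot(inherits(dataset, "pair_dataset"))
  recs <- dataset$records
  st <- recs$source_tokens
  recs$source_tokens <- recs$target_tokens
  recs$target_tokens <- st
  structure(list(records = recs,
                 source_side = dataset$target_side,
                 target_side = dataset$source_side,
                 max_source_len = dataset$max_target_len,
                 max_target_len = dataset$max_source_len,
                 n_dropped = dataset$n_dropped),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset> %s -> %s: %d records (%d dropped), limits %d/%d\n",
              x$source_side, x$target_side, nrow(x$records), x$n_dropped,
              x$max_source_len, x$max_target_len))
  invisible(x)
}

# Relative token frequency vector over a fixed token universe.
.token_freq <- function(token_lists, universe) {
  counts <- table(factor(unlist(token_lists), levels = universe))
  as.numeric(counts) / max(1, sum(counts))
}

#' Split a pair dataset into train and test portions
#'
#' The split is seed-deterministic and re-drawn (with an incremented
#' seed, bounded retries) until two balance conditions hold: every source
#' token occurring in the test portion also occurs in the training
#' portion, and the relative token-frequency vectors of the two portions
#' have cosine similarity of at least `min_cosine`. This mirrors a test
#' set whose token distribution closely matches the training data.
#'
#' @param dataset a `pair_dataset`.
#' @param test_fraction fraction of records assigned to the test set.
#' @param seed integer seed.
#' @param min_cosine required cosine similarity of token frequencies.
#' @param max_retries how many incremented seeds to try.
#' @return list with `train` and `test` pair datasets and the `seed` used.
#' @export
split_train_test <- function(dataset, test_fraction, seed,
                             min_cosine = 0.99, max_retries = 25L) {
  stopifnot(inherits(dataset, "pair_dataset"))
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  n <- nrow(dataset$records)
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) stop("dataset too small for the requested split")
  universe <- sort(unique(unlist(dataset$records$source_tokens)))
  for (k in 0:max_retries) {
    idx <- withr::with_seed(seed + k, sample.int(n, n_test))
    tr <- dataset$records[-idx, ]
    te <- dataset$records[idx, ]
    cover <- all(unique(unlist(te$source_tokens)) %in%
                   unlist(tr$source_tokens))
    f1 <- .token_freq(tr$source_tokens, universe)
    f2 <- .token_freq(te$source_tokens, universe)
    cosine <- sum(f1 * f2) / sqrt(sum(f1^2) * sum(f2^2))
    if (cover && cosine >= min_cosine) {
      sub <- function(recs) {
        out <- dataset
        out$records <- recs
        out$n_dropped <- 0L
        out
      }
      return(list(train = sub(tr), test = sub(te), seed = seed + k,
                  cosine = cosine))
    }
  }
  stop("could not produce a token-covering, distribution-matched split")
}

#' Write a paired corpus to a tab-separated file
#'
#' Columns `smiles`, `selfies`, `name`, UTF-8, LF line endings.
#'
#' @param records tibble with those columns.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pair_file <- function(records, path) {
  stopifnot(all(c("smiles", "selfies", "name") %in% names(records)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("smiles\tselfies\tname",
               paste(records$smiles, records$selfies, records$name,
                     sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a paired corpus written by [write_pair_file()]
#'
#' @param path input file path.
#' @return tibble with columns `smiles`, `selfies`, `name`.
#' @export
read_pair_file <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                      colClasses = "character"))
}

#' Write a filter drop-log (rejected SMILES and the rule violated)
#'
#' @param data tibble from [filter_molecules()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_drop_log <- function(data, path) {
  dropped <- data[!is.na(data$accepted) & !data$accepted |
                    is.na(data$accepted), c("smiles", "violated_rule")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("smiles\tviolated_rule",
               paste(dropped$smiles, dropped$violated_rule, sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
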