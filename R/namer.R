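# Rule-based substitutive nomenclature for a restricted acyclic family:
# alkane parents with methyl/ethyl branches and hydroxy/amino/halo/oxo
# substituents. The namer and the name parser are exact inverses on the
# family, which is what makes generated corpora exact ground truth.

.chain_stems <- c("meth", "eth", "prop", "but", "pent", "hex", "hept",
                  "oct", "non", "dec", "undec", "dodec")
.multipliers <- c("", "di", "tri", "tetra")

.substituent_info <- list(
  methyl = list(kind = "alkyl", frag = "C"),
  ethyl = list(kind = "alkyl", frag = "CC"),
  hydroxy = list(kind = "hetero", frag = "O", suffix = "ol", priority = 2),
  amino = list(kind = "hetero", frag = "N", suffix = "amine", priority = 1),
  chloro = list(kind = "hetero", frag = "Cl"),
  bromo = list(kind = "hetero", frag = "Br"),
  fluoro = list(kind = "hetero", frag = "F"),
  iodo = list(kind = "hetero", frag = "I"),
  oxo = list(kind = "oxo", frag = "=O", suffix = "one", priority = 3)
)

#' Family specification for the synthetic molecule generator
#'
#' @param max_chain_length longest carbon backbone sampled (<= 12).
#' @param substituents subset of methyl, ethyl, hydroxy, amino, chloro,
#'   bromo, fluoro, iodo, oxo.
#' @param max_substituents most substituents per molecule.
#' @param seed integer seed driving generation.
#' @return a `family_spec` list.
#' @export
family_spec <- function(max_chain_length = 8L,
                        substituents = c("methyl", "hydroxy"),
                        max_substituents = 3L, seed = 1L) {
  stopifnot(max_chain_length >= 2, max_chain_length <= 12)
  bad <- setdiff(substituents, names(.substituent_info))
  if (length(bad) > 0) stop("unknown substituents: ", paste(bad, collapse = ", "))
  structure(list(max_chain_length = as.integer(max_chain_length),
                 substituents = substituents,
                 max_substituents = as.integer(max_substituents),
                 seed = as.integer(seed)),
            class = "family_spec")
}

# Build a SMILES string for a chain of length n with substituents given
# as a list of (position, name) pairs.
.assemble_smiles <- function(n, subs) {
  frags <- vector("list", n)
  if (length(subs) > 0) {
    for (s in subs) {
      frags[[s$position]] <- c(frags[[s$position]],
                               .substituent_info[[s$name]]$frag)
    }
  }
  paste(vapply(seq_len(n), function(i) {
    paste0("C", paste(sprintf("(%s)", frags[[i]]), collapse = ""))
  }, character(1)), collapse = "")
}

# ---- naming ---------------------------------------------------------------

# Decompose a family molecule graph around one candidate parent chain.
# Returns NULL when the candidate cannot express the molecule in the
# family grammar (substituted branches or off-chain heteroatoms).
.chain_decomposition <- function(g, adj, chain) {
  n <- length(chain)
  on_chain <- logical(nrow(g$atoms))
  on_chain[chain] <- TRUE
  subs <- list()
  for (pos in seq_len(n)) {
    a <- chain[pos]
    nb <- adj[[a]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      b <- nb[k, 1]; o <- nb[k, 2]
      if (on_chain[b]) {
        if (o != 1) return(NULL)  # multiple bond inside the chain
        next
      }
      el <- g$atoms$element[b]
      if (el == "C") {
        if (o != 1) return(NULL)
        # branch must be an unsubstituted methyl or ethyl
        br <- adj[[b]]
        others <- br[br[, 1] != a, , drop = FALSE]
        if (nrow(others) == 0) {
          subs[[length(subs) + 1]] <- list(position = pos, name = "methyl")
        } else if (nrow(others) == 1 && others[1, 2] == 1 &&
                   g$atoms$element[others[1, 1]] == "C") {
          b2 <- others[1, 1]
          br2 <- adj[[b2]]
          if (nrow(br2[br2[, 1] != b, , drop = FALSE]) > 0) return(NULL)
          subs[[length(subs) + 1]] <- list(position = pos, name = "ethyl")
        } else {
          return(NULL)
        }
      } else if (el == "O" && o == 2) {
        if (pos == 1 || pos == n) return(NULL)  # aldehyde: out of family
        subs[[length(subs) + 1]] <- list(position = pos, name = "oxo")
      } else if (el == "O" && o == 1) {
        subs[[length(subs) + 1]] <- list(position = pos, name = "hydroxy")
      } else if (el == "N" && o == 1) {
        subs[[length(subs) + 1]] <- list(position = pos, name = "amino")
      } else if (el %in% c("F", "Cl", "Br", "I") && o == 1) {
        subs[[length(subs) + 1]] <- list(
          position = pos,
          name = c(F = "fluoro", Cl = "chloro", Br = "bromo",
                   I = "iodo")[[el]])
      } else {
        return(NULL)
      }
    }
  }
  subs
}

# Assemble a name from a chain length and substituent list; returns the
# name plus the sort keys used for candidate selection.
.assemble_name <- function(n, subs) {
  names_ <- vapply(subs, `[[`, character(1), "name")
  pos_ <- vapply(subs, `[[`, numeric(1), "position")
  prios <- vapply(names_, function(nm) {
    p <- .substituent_info[[nm]]$priority
    if (is.null(p)) 0 else p
  }, numeric(1))
  principal <- if (any(prios > 0)) names_[which.max(prios)] else NA_character_
  is_suffix <- !is.na(principal) & names_ == principal
  suffix_loc <- sort(pos_[is_suffix])
  prefix_tbl <- data.frame(name = names_[!is_suffix], pos = pos_[!is_suffix],
                           stringsAsFactors = FALSE)
  stem <- .chain_stems[n]
  omit_locants <- n <= 2 && length(subs) == 1

  units <- character(0)
  if (nrow(prefix_tbl) > 0) {
    for (nm in sort(unique(prefix_tbl$name))) {
      locs <- sort(prefix_tbl$pos[prefix_tbl$name == nm])
      mult <- .multipliers[length(locs)]
      if (length(locs) > 4) return(NULL)
      units <- c(units, if (omit_locants) paste0(mult, nm) else
        sprintf("%s-%s%s", paste(locs, collapse = ","), mult, nm))
    }
  }
  if (is.na(principal)) {
    parent <- paste0(stem, "ane")
  } else {
    suff <- .substituent_info[[principal]]$suffix
    if (length(suffix_loc) > 4) return(NULL)
    mult <- .multipliers[length(suffix_loc)]
    if (omit_locants) {
      parent <- paste0(stem, "an", suff)
    } else if (nzchar(mult)) {
      parent <- sprintf("%sane-%s-%s%s", stem,
                        paste(suffix_loc, collapse = ","), mult, suff)
    } else {
      parent <- sprintf("%san-%d-%s", stem, suffix_loc, suff)
    }
  }
  # citation order: prefixes alphabetically, then the parent appended
  # directly to the last prefix (2-methylpropane, not 2-methyl-propane)
  name <- paste0(paste(units, collapse = "-"), parent)
  prefix_locs <- sort(prefix_tbl$pos)
  list(name = name,
       key = list(suffix = suffix_loc, prefix = prefix_locs))
}

#' Systematic name of a family molecule
#'
#' Longest-chain parent selection, lowest locants by first point of
#' difference (principal characteristic group first), alphabetical
#' substituent citation ignoring multiplying prefixes, and the suffix
#' priority ketone > alcohol > amine.
#'
#' @param smiles a single SMILES string inside the family.
#' @return the systematic name string.
#' @export
name_molecule <- function(smiles) {
  g <- mol_graph(smiles)
  n_at <- nrow(g$atoms)
  if (n_at == 0) stop("empty structure")
  if (nrow(g$bonds) != n_at - 1) {
    stop("unsupported structure: must be connected and acyclic",
         call. = FALSE)
  }
  if (any(g$atoms$charge != 0) || any(g$atoms$isotope != 0)) {
    stop("unsupported structure: charges/isotopes outside the family",
         call. = FALSE)
  }
  if (!all(g$atoms$element %in% c("C", "N", "O", "F", "Cl", "Br", "I"))) {
    stop("unsupported structure: element outside the family", call. = FALSE)
  }
  adj <- graph_adjacency(g)
  carbons <- which(g$atoms$element == "C")
  if (length(carbons) == 0) stop("unsupported structure: no carbon skeleton",
                                 call. = FALSE)

  # all simple paths between carbon pairs (the skeleton is a tree, so
  # each pair has exactly one path)
  cpath <- function(a, b) {
    # BFS on carbon subgraph
    parent <- rep(NA_integer_, nrow(g$atoms))
    seen <- logical(nrow(g$atoms)); seen[a] <- TRUE
    queue <- a
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        w <- nb[k, 1]
        if (!seen[w] && g$atoms$element[w] == "C") {
          seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
        }
      }
    }
    if (!seen[b]) return(NULL)
    path <- b
    while (path[1] != a) path <- c(parent[path[1]], path)
    path
  }
  paths <- list()
  if (length(carbons) == 1) {
    paths <- list(carbons)
  } else {
    for (i in seq_along(carbons)) {
      for (j in seq_along(carbons)) {
        if (i == j) next
        p <- cpath(carbons[i], carbons[j])
        if (!is.null(p)) paths[[length(paths) + 1]] <- p
      }
    }
  }
  maxlen <- max(lengths(paths))
  if (maxlen > length(.chain_stems)) {
    stop("unsupported structure: chain too long", call. = FALSE)
  }
  cands <- paths[lengths(paths) == maxlen]

  best <- NULL
  for (chain in cands) {
    subs <- .chain_decomposition(g, adj, chain)
    if (is.null(subs) && length(chain) > 0) next
    nm <- .assemble_name(length(chain), subs)
    if (is.null(nm)) next
    if (is.null(best) || .name_key_less(nm, best)) best <- nm
  }
  if (is.null(best)) {
    stop("unsupported structure: no parent chain expresses the molecule",
         call. = FALSE)
  }
  best$name
}

# Candidate comparison: lowest suffix locants, then lowest prefix
# locants (first point of difference), then the lexicographically
# smallest name.
.name_key_less <- function(a, b) {
  cmp_vec <- function(x, y) {
    l <- max(length(x), length(y))
    x <- c(x, rep(Inf, l - length(x)))
    y <- c(y, rep(Inf, l - length(y)))
    d <- which(x != y)
    if (length(d) == 0) 0 else if (x[d[1]] < y[d[1]]) -1 else 1
  }
  s <- cmp_vec(a$key$suffix, b$key$suffix)
  if (s != 0) return(s < 0)
  p <- cmp_vec(a$key$prefix, b$key$prefix)
  if (p != 0) return(p < 0)
  a$name < b$name
}

# ---- parsing --------------------------------------------------------------

.invalid_name <- function(name, why) {
  stop(structure(class = c("chemnmt_invalid_name", "error", "condition"),
                 list(message = sprintf("invalid name '%s': %s", name, why),
                      call = NULL)))
}

#' Parse a family name back to a structure
#'
#' Inverse of [name_molecule()] on the family grammar. Ungrammatical or
#' chemically impossible names raise an error of class
#' `chemnmt_invalid_name` - the signal counted as an invalid prediction
#' during evaluation.
#'
#' @param name a systematic name produced by the family grammar.
#' @return the canonical SMILES of the named structure.
#' @export
parse_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  sub_alt <- "methyl|ethyl|hydroxy|amino|chloro|bromo|fluoro|iodo|oxo"

  # parse the leading prefix-unit section; NULL when ungrammatical
  parse_prefixes <- function(rest, n) {
    subs <- list()
    while (nzchar(rest)) {
      m <- regmatches(rest, regexec(sprintf(
        "^(\\d+(?:,\\d+)*)-(di|tri|tetra)?(%s)-?", sub_alt), rest))[[1]]
      if (length(m) > 0) {
        locs <- as.integer(strsplit(m[2], ",", fixed = TRUE)[[1]])
        mult <- if (nzchar(m[3])) m[3] else ""
        if (match(mult, .multipliers) != length(locs)) return(NULL)
        for (p in locs) {
          subs[[length(subs) + 1]] <- list(position = p, name = m[4])
        }
        rest <- substring(rest, nchar(m[1]) + 1L)
        next
      }
      m <- regmatches(rest, regexec(sprintf("^(%s)$", sub_alt), rest))[[1]]
      if (length(m) > 0 && n <= 2) {
        subs[[length(subs) + 1]] <- list(position = 1L, name = m[2])
        rest <- ""
        next
      }
      return(NULL)
    }
    subs
  }

  sufname <- c(ol = "hydroxy", one = "oxo", amine = "amino")
  tails <- list(  # sprintf templates over the stem; groups after the stem
    plain = "^(.*)%sane$",
    suffix1 = "^(.*)%san-(\\d+)-(ol|one|amine)$",
    suffixn = "^(.*)%sane-(\\d+(?:,\\d+)+)-(di|tri|tetra)(ol|one|amine)$",
    bare = "^(.*)%san(ol|one|amine)$"
  )
  # substituent names can fabricate spurious stem substrings (iodo +
  # decane reads as dodecane), so every (kind, stem) split is tried and
  # the first fully grammatical parse wins
  subs <- NULL; n <- NA_integer_
  for (kind in names(tails)) {
    for (stem in .chain_stems[order(-nchar(.chain_stems))]) {
      m <- regmatches(name, regexec(sprintf(tails[[kind]], stem), name))[[1]]
      if (length(m) == 0) next
      n_try <- match(stem, .chain_stems)
      suffix_subs <- list()
      if (kind == "suffix1") {
        suffix_subs <- list(list(position = as.integer(m[3]),
                                 name = sufname[[m[4]]]))
      } else if (kind == "suffixn") {
        locs <- as.integer(strsplit(m[3], ",", fixed = TRUE)[[1]])
        if (match(m[4], .multipliers) != length(locs)) next
        suffix_subs <- lapply(locs, function(p) {
          list(position = p, name = sufname[[m[5]]])
        })
      } else if (kind == "bare") {
        if (n_try > 2) next
        suffix_subs <- list(list(position = 1L, name = sufname[[m[3]]]))
      }
      pre <- parse_prefixes(m[2], n_try)
      if (is.null(pre)) next
      subs <- c(suffix_subs, pre)
      n <- n_try
      break
    }
    if (!is.na(n)) break
  }
  if (is.na(n)) .invalid_name(name, "not parseable in the family grammar")

  # chemical validation
  free <- c(3, rep(2, max(0, n - 2)), if (n > 1) 3)[seq_len(n)]
  if (n == 1) free <- 4
  for (s in subs) {
    p <- s$position
    if (p < 1 || p > n) .invalid_name(name, "locant outside the chain")
    cost <- if (s$name == "oxo") 2 else 1
    if (s$name == "oxo" && (p == 1 || p == n) && n > 1) {
      .invalid_name(name, "oxo on a terminal carbon")
    }
    free[p] <- free[p] - cost
    if (free[p] < 0) .invalid_name(name, "valence exceeded")
  }
  smi <- .assemble_smiles(n, subs)
  canonical_smiles(smi)
}

# ---- generation -----------------------------------------------------------

#' Generate distinct family molecules
#'
#' Seed-deterministic rejection sampling inside the family: every
#' returned SMILES passes the default corpus filter, is canonically
#' unique, and is nameable by [name_molecule()].
#'
#' @param spec a [family_spec()].
#' @param n number of distinct molecules.
#' @param rules filter ruleset the molecules must pass.
#' @return character vector of n canonical SMILES.
#' @export
generate_molecules <- function(spec, n, rules = filter_rules()) {
  stopifnot(inherits(spec, "family_spec"), n >= 1)
  out <- character(0)
  withr::with_seed(spec$seed, {
    attempts <- 0L
    max_attempts <- 400L * n
    while (length(out) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      len <- sample(2:spec$max_chain_length, 1)
      k <- sample(0:spec$max_substituents, 1)
      free <- c(3, rep(2, max(0, len - 2)), if (len > 1) 3)[seq_len(len)]
      hetero_used <- logical(len)
      subs <- list()
      ok <- TRUE
      if (k > 0) {
        for (j in seq_len(k)) {
          nm <- sample(spec$substituents, 1)
          info <- .substituent_info[[nm]]
          cost <- if (nm == "oxo") 2 else 1
          cand_pos <- which(free >= cost)
          if (nm == "oxo") cand_pos <- setdiff(cand_pos, c(1L, len))
          if (info$kind != "alkyl") cand_pos <- cand_pos[!hetero_used[cand_pos]]
          if (length(cand_pos) == 0) { ok <- FALSE; break }
          p <- if (length(cand_pos) == 1) cand_pos else sample(cand_pos, 1)
          free[p] <- free[p] - cost
          if (info$kind != "alkyl") hetero_used[p] <- TRUE
          subs[[length(subs) + 1]] <- list(position = p, name = nm)
        }
      }
      if (!ok) next
      smi <- canonical_smiles(.assemble_smiles(len, subs))
      if (is.na(smi) || smi %in% out) next
      verdict <- tryCatch(apply_filter_rules(smi, rules),
                          error = function(e) list(accepted = FALSE))
      if (!isTRUE(verdict$accepted)) next
      nameable <- tryCatch({ name_molecule(smi); TRUE },
                           error = function(e) FALSE)
      if (!nameable) next
      out <- c(out, smi)
    }
  })
  if (length(out) < n) {
    stop(sprintf("family exhausted: only %d distinct molecules found (%d wanted)",
                 length(out), n), call. = FALSE)
  }
  out
}

#' Generate a paired (structure, name, SELFIES) corpus
#'
#' @param spec a [family_spec()].
#' @param n number of pairs.
#' @return tibble with columns `smiles`, `selfies`, `name`; every name
#'   re-parses to its own structure and both token-length limits hold.
#' @export
generate_pair_corpus <- function(spec, n) {
  smi <- generate_molecules(spec, n)
  tibble::tibble(
    smiles = smi,
    selfies = vapply(smi, smiles_to_selfies, character(1), USE.NAMES = FALSE),
    name = vapply(smi, name_molecule, character(1), USE.NAMES = FALSE)
  )
}
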