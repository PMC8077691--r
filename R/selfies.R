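# SELFIES-style robust molecular string representation.
#
# The package implements its own SELFIES dialect: every string of tokens
# over the alphabet decodes to a chemically valid structure, because bond
# orders are capped by the remaining valence of both partner atoms during
# derivation and tokens that cannot be realized are skipped. Token names
# follow the classic bracketed style ([C], [=O], [Branch1_1], [Ring1],
# [Expl=Ring1], ...), so printed corpora look like the familiar form.

.selfies_valence <- c(B = 3, C = 4, N = 3, O = 2, S = 6, P = 5,
                      F = 1, Cl = 1, Br = 1, I = 1, Se = 6)

# Index alphabet: the token following a Branch/Ring token encodes an
# integer 0..15 through its position in this list (two tokens encode
# base-16 numbers for Branch2/Ring2).
.selfies_index_alphabet <- c(
  "[C]", "[Ring1]", "[Ring2]", "[Branch1_1]", "[Branch1_2]", "[Branch1_3]",
  "[Branch2_1]", "[Branch2_2]", "[Branch2_3]", "[O]", "[N]", "[=N]",
  "[=C]", "[#C]", "[S]", "[P]"
)

#' The SELFIES token alphabet used by this package
#'
#' @return character vector of all tokens the decoder understands.
#' @export
selfies_alphabet <- function() {
  atoms <- names(.selfies_valence)
  atom_tokens <- c(paste0("[", atoms, "]"),
                   paste0("[=", atoms[.selfies_valence[atoms] >= 2], "]"),
                   paste0("[#", atoms[.selfies_valence[atoms] >= 3], "]"))
  unique(c(atom_tokens,
           "[Branch1_1]", "[Branch1_2]", "[Branch1_3]",
           "[Branch2_1]", "[Branch2_2]", "[Branch2_3]",
           "[Ring1]", "[Ring2]", "[Expl=Ring1]", "[Expl#Ring1]",
           "[Expl=Ring2]"))
}

.parse_selfies_tokens <- function(selfies) {
  if (!nzchar(selfies)) return(character(0))
  if (!grepl("^(\\[[^][]*\\])+$", selfies)) {
    stop("malformed SELFIES: not a concatenation of bracketed tokens",
         call. = FALSE)
  }
  regmatches(selfies, gregexpr("\\[[^][]*\\]", selfies))[[1]]
}

.index_value <- function(token) {
  i <- match(token, .selfies_index_alphabet)
  if (is.na(i)) 0L else i - 1L
}

.index_token <- function(value) .selfies_index_alphabet[value + 1L]

# ---- decoding -------------------------------------------------------------

# Derivation state: atoms (element vector), bonds, free valence per atom.
# Returns the mol_graph; robust by construction.
.decode_tokens <- function(tokens) {
  elements <- character(0)
  free <- numeric(0)
  bonds <- list()
  bond_keys <- character(0)  # one bond per atom pair

  add_bond <- function(a, b, order) {
    bonds[[length(bonds) + 1]] <<- c(a, b, order)
    bond_keys <<- c(bond_keys, paste(min(a, b), max(a, b), sep = "-"))
    free[a] <<- free[a] - order
    free[b] <<- free[b] - order
  }

  # consume tokens starting at position i, attached to atom `anchor`;
  # stops after `limit` tokens (NA = run to the end). Returns next i.
  derive <- function(i, anchor, limit) {
    used <- 0L
    current <- anchor
    while (i <= length(tokens) && (is.na(limit) || used < limit)) {
      tk <- tokens[i]; i <- i + 1L; used <- used + 1L
      m <- regmatches(tk, regexec("^\\[([=#]?)([A-Za-z][a-z]?)\\]$", tk))[[1]]
      if (length(m) > 0 && m[3] %in% names(.selfies_valence)) {
        elem <- m[3]
        want <- c(1, 2, 3)[match(m[2], c("", "=", "#"))]
        cap <- .selfies_valence[[elem]]
        if (is.na(current)) {
          elements <<- c(elements, elem); free <<- c(free, cap)
          current <- length(elements)
        } else {
          ord <- min(want, free[current], cap)
          if (ord >= 1) {
            elements <<- c(elements, elem); free <<- c(free, cap)
            add_bond(current, length(elements), ord)
            current <- length(elements)
          }  # else: skip token (no capacity)
        }
        next
      }
      bm <- regmatches(tk, regexec("^\\[Branch([12])_([123])\\]$", tk))[[1]]
      if (length(bm) > 0) {
        if (is.na(current)) {
          # no anchor atom yet: only the marker itself is void; index and
          # content tokens are processed normally so atoms are never lost
          next
        }
        nidx <- as.integer(bm[2])
        border <- as.integer(bm[3])
        if (i + nidx - 1L > length(tokens)) break
        q <- 0L
        for (k in seq_len(nidx)) {
          q <- q * 16L + .index_value(tokens[i]); i <- i + 1L; used <- used + 1L
        }
        len <- q + 1L
        if (free[current] >= 1) derive_branch(i, current, len, border)
        skip <- min(len, length(tokens) - i + 1L)
        i <- i + skip; used <- used + skip
        next
      }
      rm_ <- regmatches(tk, regexec("^\\[(Expl([=#]))?Ring([12])\\]$", tk))[[1]]
      if (length(rm_) > 0) {
        if (is.na(current)) next  # marker-only skip, as for branches
        want <- if (rm_[3] == "=") 2 else if (rm_[3] == "#") 3 else 1
        nidx <- as.integer(rm_[4])
        if (i + nidx - 1L > length(tokens)) break
        q <- 0L
        for (k in seq_len(nidx)) {
          q <- q * 16L + .index_value(tokens[i]); i <- i + 1L; used <- used + 1L
        }
        if (!is.na(current)) {
          target <- current - (q + 1L)
          key <- paste(min(target, current), max(target, current), sep = "-")
          if (target >= 1 && target != current && !(key %in% bond_keys)) {
            ord <- min(want, free[current], free[target])
            if (ord >= 1) add_bond(target, current, ord)
          }
        }
        next
      }
      # unknown token: skipped (robustness)
    }
    i
  }

  # branch derivation shares global atom numbering; bond order of the
  # branch attachment is the Branch token's order, capped by valence.
  derive_branch <- function(i, anchor, len, border) {
    saved_tokens <- tokens[seq(i, length.out = min(len, length(tokens) - i + 1L))]
    if (length(saved_tokens) == 0) return(i)
    # first atom token in branch attaches with `border` (its own prefix,
    # if any, takes precedence)
    first <- saved_tokens[1]
    m <- regmatches(first, regexec("^\\[([=#]?)([A-Za-z][a-z]?)\\]$", first))[[1]]
    if (length(m) > 0 && m[3] %in% names(.selfies_valence)) {
      elem <- m[3]
      want <- if (m[2] == "=") 2 else if (m[2] == "#") 3 else border
      cap <- .selfies_valence[[elem]]
      ord <- min(want, free[anchor], cap)
      if (ord >= 1) {
        elements <<- c(elements, elem); free <<- c(free, cap)
        add_bond(anchor, length(elements), ord)
        if (length(saved_tokens) > 1) {
          derive(i + 1L, length(elements), length(saved_tokens) - 1L)
        }
      }
    } else {
      derive(i, anchor, length(saved_tokens))
    }
    i + length(saved_tokens)
  }

  derive(1L, NA_integer_, NA)
  atoms <- tibble::tibble(element = elements,
                          charge = rep(0L, length(elements)),
                          isotope = rep(0L, length(elements)))
  bonds <- if (length(bonds) > 0) {
    m <- do.call(rbind, bonds)
    tibble::tibble(from = as.integer(m[, 1]), to = as.integer(m[, 2]),
                   order = as.integer(m[, 3]))
  } else tibble::tibble(from = integer(), to = integer(), order = integer())
  atoms$hcount <- implicit_hydrogens(atoms, bonds)
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

#' Decode a SELFIES string to a SMILES string
#'
#' Decoding is total over well-formed token strings: bond orders are
#' capped by remaining valences and unrealizable tokens are skipped, so
#' every token string yields a valid structure.
#'
#' @param selfies a SELFIES string (concatenated bracketed tokens).
#' @return a canonical SMILES string ("" for an empty derivation).
#' @export
selfies_to_smiles <- function(selfies) {
  tokens <- .parse_selfies_tokens(selfies)
  if (length(tokens) == 0) return("")
  g <- .decode_tokens(tokens)
  if (nrow(g$atoms) == 0) return("")
  graph_to_smiles(g)
}

# ---- encoding -------------------------------------------------------------

#' Encode a SMILES string as SELFIES
#'
#' The returned string decodes back to a structure canonically identical
#' to the input. Charged atoms, isotopes and elements outside the
#' alphabet are not encodable and raise a conversion error.
#'
#' @param smiles a single SMILES string.
#' @return a SELFIES string.
#' @export
smiles_to_selfies <- function(smiles) {
  g <- mol_graph(smiles)
  if (nrow(g$atoms) == 0) stop("empty structure cannot be encoded")
  if (any(g$atoms$charge != 0) || any(g$atoms$isotope != 0)) {
    stop("structure outside the SELFIES alphabet (charge/isotope)",
         call. = FALSE)
  }
  if (!all(g$atoms$element %in% names(.selfies_valence))) {
    stop("structure outside the SELFIES alphabet (element)", call. = FALSE)
  }
  if (any(g$bonds$order > 3)) {
    stop("aromatic bond orders must be kekulized before encoding",
         call. = FALSE)
  }
  adj <- graph_adjacency(g)
  n <- nrow(g$atoms)
  visited <- logical(n)
  derive_pos <- integer(n)  # atom -> derivation order position
  counter <- 0L

  prefix_tok <- function(order, elem) {
    p <- c("", "=", "#")[order]
    paste0("[", p, elem, "]")
  }

  seen_edges <- new.env(parent = emptyenv())
  .edge_key <- function(a, b) paste(min(a, b), max(a, b), sep = "-")
  .edge_unseen <- function(a, b) is.null(seen_edges[[.edge_key(a, b)]])
  .mark_edge <- function(a, b) assign(.edge_key(a, b), TRUE, envir = seen_edges)

  # DFS with live neighbor iteration: every non-tree edge is then a back
  # edge to an ancestor, which is exactly what Ring tokens express.
  encode_atom <- function(a, incoming_order) {
    visited[a] <<- TRUE
    counter <<- counter + 1L
    derive_pos[a] <<- counter
    atom_tok <- prefix_tok(incoming_order, g$atoms$element[a])
    nb <- adj[[a]]
    ring_toks <- character(0)
    child_parts <- list()
    child_orders <- integer(0)
    if (!is.null(nb)) {
      for (k in seq_len(nrow(nb))) {
        b <- nb[k, 1]; o <- nb[k, 2]
        if (!.edge_unseen(a, b)) next
        if (visited[b]) {
          .mark_edge(a, b)
          offset <- derive_pos[a] - derive_pos[b] - 1L
          ring_toks <- c(ring_toks, .ring_tokens(offset, o))
        } else {
          .mark_edge(a, b)
          child_parts[[length(child_parts) + 1]] <- encode_atom(b, o)
          child_orders <- c(child_orders, o)
        }
      }
    }
    tokens <- c(atom_tok, ring_toks)
    nc <- length(child_parts)
    if (nc > 0) {
      for (j in seq_len(nc)) {
        if (j < nc) {
          tokens <- c(tokens, .branch_tokens(child_parts[[j]],
                                             child_orders[j]))
        } else {
          tokens <- c(tokens, child_parts[[j]])
        }
      }
    }
    tokens
  }

  .branch_tokens <- function(content, order) {
    len <- length(content)
    # strip the bond prefix of the first token: the Branch token carries it
    first <- content[1]
    stripped <- sub("^\\[[=#]", "[", first)
    content[1] <- stripped
    if (len <= 16L) {
      c(sprintf("[Branch1_%d]", order), .index_token(len - 1L), content)
    } else if (len <= 256L) {
      q <- len - 1L
      c(sprintf("[Branch2_%d]", order),
        .index_token(q %/% 16L), .index_token(q %% 16L), content)
    } else {
      stop("branch too long to encode")
    }
  }

  .ring_tokens <- function(offset, order) {
    head <- if (order == 1) "[Ring%d]" else if (order == 2) "[Expl=Ring%d]"
      else "[Expl#Ring%d]"
    if (offset <= 15L) {
      c(sprintf(head, 1L), .index_token(offset))
    } else if (offset <= 255L) {
      c(sprintf(head, 2L), .index_token(offset %/% 16L),
        .index_token(offset %% 16L))
    } else {
      stop("ring span too long to encode")
    }
  }

  if (length(unique(c(1L, if (nrow(g$bonds)) c(g$bonds$from, g$bonds$to)))) <
      n && n > 1 && nrow(g$bonds) < n - 1) {
    stop("disconnected structures cannot be encoded", call. = FALSE)
  }
  tokens <- encode_atom(1L, 1L)
  tokens[1] <- sub("^\\[[=#]", "[", tokens[1])
  if (any(!visited)) stop("disconnected structures cannot be encoded",
                          call. = FALSE)
  paste(tokens, collapse = "")
}
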