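# 881-bit substructure-key fingerprint (PubChem/CACTVS layout),
# bit-Tanimoto similarity and graph-identity checks.

# Smallest set of smallest rings (greedy): shortest cycle through each
# edge, collected until the cyclomatic number is reached. Exact for the
# small molecules this package works with.
.sssr <- function(g) {
  n <- nrow(g$atoms)
  nb <- nrow(g$bonds)
  if (nb < n) return(list())  # acyclic (or disconnected without cycles)
  adj <- vector("list", n)
  for (i in seq_len(nb)) {
    adj[[g$bonds$from[i]]] <- c(adj[[g$bonds$from[i]]], g$bonds$to[i])
    adj[[g$bonds$to[i]]] <- c(adj[[g$bonds$to[i]]], g$bonds$from[i])
  }
  shortest_cycle_through <- function(a, b) {
    # BFS from a to b avoiding the direct edge a-b
    dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
    dist[a] <- 0L
    queue <- a
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == a && w == b) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[b])) return(NULL)
    path <- b
    while (path[1] != a) path <- c(parent[path[1]], path)
    path
  }
  n_rings_target <- nb - n + 1L  # connected molecules
  rings <- list()
  keys <- character(0)
  cand <- list()
  for (i in seq_len(nb)) {
    cyc <- shortest_cycle_through(g$bonds$from[i], g$bonds$to[i])
    if (!is.null(cyc)) cand[[length(cand) + 1]] <- cyc
  }
  if (length(cand) == 0) return(list())
  cand <- cand[order(lengths(cand))]
  for (cyc in cand) {
    key <- paste(sort(cyc), collapse = "-")
    if (!(key %in% keys)) {
      rings[[length(rings) + 1]] <- cyc
      keys <- c(keys, key)
      if (length(rings) >= n_rings_target) break
    }
  }
  rings
}

# Classify each SSSR ring: size, composition, saturation.
.ring_table <- function(g) {
  rings <- .sssr(g)
  if (length(rings) == 0) {
    return(data.frame(size = integer(), carbon_only = logical(),
                      has_n = logical(), has_het = logical(),
                      saturated = logical()))
  }
  bond_order <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(g$bonds))) {
    k <- paste(min(g$bonds$from[i], g$bonds$to[i]),
               max(g$bonds$from[i], g$bonds$to[i]), sep = "-")
    assign(k, g$bonds$order[i], envir = bond_order)
  }
  rows <- lapply(rings, function(r) {
    el <- g$atoms$element[r]
    pairs <- cbind(r, c(r[-1], r[1]))
    ords <- apply(pairs, 1, function(p) {
      get(paste(min(p), max(p), sep = "-"), envir = bond_order)
    })
    data.frame(size = length(r), carbon_only = all(el == "C"),
               has_n = any(el == "N"), has_het = any(el != "C"),
               saturated = all(ords == 1))
  })
  do.call(rbind, rows)
}

# Aromatic ring counts per size via SMARTS on the Open Babel molecule.
.aromatic_ring_counts <- function(sdf_text) {
  sizes <- 3:10
  all_pat <- vapply(sizes, function(k) {
    paste0("a1", paste(rep("a", k - 1), collapse = ""), "1")
  }, character(1))
  c_pat <- vapply(sizes, function(k) {
    paste0("c1", paste(rep("c", k - 1), collapse = ""), "1")
  }, character(1))
  non_n_pat <- vapply(sizes, function(k) {
    paste0("[a;!#7]1", paste(rep("[a;!#7]", k - 1), collapse = ""), "1")
  }, character(1))
  total <- smarts_counts(sdf_text, all_pat, format = "SDF")
  carbon <- smarts_counts(sdf_text, c_pat, format = "SDF")
  no_n <- smarts_counts(sdf_text, non_n_pat, format = "SDF")
  data.frame(size = sizes, total = total, carbon = carbon,
             nitro = pmax(0L, total - no_n), het = pmax(0L, total - carbon))
}

# Section 2 ring bits (148), following the published layout: per ring
# size, seven category counts at one or more count levels, then eight
# aromatic/hetero-aromatic count bits.
.ring_bits <- function(g, sdf_text) {
  rt <- .ring_table(g)
  any_rings <- nrow(rt) > 0
  ar <- if (any_rings) .aromatic_ring_counts(sdf_text) else
    data.frame(size = 3:10, total = 0L, carbon = 0L, nitro = 0L, het = 0L)
  levels_per_size <- c(`3` = 2L, `4` = 2L, `5` = 5L, `6` = 5L, `7` = 2L,
                       `8` = 2L, `9` = 1L, `10` = 1L)
  bits <- logical(0)
  for (sz in 3:10) {
    srt <- rt[rt$size == sz, , drop = FALSE]
    arow <- ar[ar$size == sz, ]
    n_any <- nrow(srt)
    sat_c <- sum(srt$saturated & srt$carbon_only) + arow$carbon
    sat_n <- sum(srt$saturated & srt$has_n) + arow$nitro
    sat_h <- sum(srt$saturated & srt$has_het) + arow$het
    uns_c <- max(0L, sum(!srt$saturated & srt$carbon_only) - arow$carbon)
    uns_n <- max(0L, sum(!srt$saturated & srt$has_n) - arow$nitro)
    uns_h <- max(0L, sum(!srt$saturated & srt$has_het) - arow$het)
    counts <- c(n_any, sat_c, sat_n, sat_h, uns_c, uns_n, uns_h)
    for (lev in seq_len(levels_per_size[[as.character(sz)]])) {
      bits <- c(bits, counts >= lev)
    }
  }
  n_arom <- sum(ar$total)
  n_het_arom <- sum(ar$het)
  for (lev in 1:4) {
    bits <- c(bits, n_arom >= lev, n_het_arom >= lev)
  }
  bits
}

#' Substructure-key fingerprint of a molecule
#'
#' Computes the 881-bit substructure fingerprint in the PubChem/CACTVS
#' key layout: hierarchic element counts, ring counts, simple atom
#' pairs, atom nearest-neighbor and detailed-neighborhood keys, and two
#' banks of SMARTS patterns. Identical canonical structures always get
#' identical bit vectors.
#'
#' @param smiles a single SMILES string.
#' @return a `structure_fingerprint`: logical vector of length 881 with
#'   the input SMILES as attribute.
#' @export
pubchem_fingerprint <- function(smiles) {
  cached <- .fp_cache[[smiles]]
  if (!is.null(cached)) return(cached)
  g <- mol_graph(smiles)
  sdf_plain <- graph_to_sdf_text(g)
  sdf_h <- graph_to_sdf_text(g, explicit_h = TRUE)

  elem_counts <- table(g$atoms$element)
  n_h <- sum(g$atoms$hcount) + sum(g$atoms$element == "H")
  count_of <- function(e) {
    if (e == "H") n_h else
      if (e %in% names(elem_counts)) as.integer(elem_counts[[e]]) else 0L
  }
  sec1 <- mapply(function(e, t) count_of(e) >= t,
                 .fp_sec1$element, .fp_sec1$threshold)

  sec2 <- .ring_bits(g, sdf_plain)

  pair_smarts <- vapply(.fp_sec3, function(p) {
    parts <- strsplit(p, "-", fixed = TRUE)[[1]]
    paste0(.fp_pattern_to_smarts(parts[1]), "~",
           .fp_pattern_to_smarts(parts[2]))
  }, character(1))
  patterns <- c(pair_smarts,
                vapply(.fp_sec4, .fp_pattern_to_smarts, character(1)),
                vapply(.fp_sec5, .fp_pattern_to_smarts, character(1)),
                vapply(.fp_sec6, .fp_pattern_to_smarts, character(1)),
                .fp_sec7)
  counts <- smarts_counts(sdf_h, patterns, format = "SDF")
  bits <- c(unname(sec1), sec2, counts >= 1L)
  stopifnot(length(bits) == 881L)
  out <- structure(as.logical(bits), class = "structure_fingerprint",
                   smiles = smiles)
  .fp_cache[[smiles]] <- out
  out
}

# fingerprints are pure functions of the input string: memoised per
# session (SMARTS evaluation dominates the cost)
.fp_cache <- new.env(parent = emptyenv())

#' @export
print.structure_fingerprint <- function(x, ...) {
  cat(sprintf("<structure_fingerprint> 881 bits, %d set (%s)\n",
              sum(x), attr(x, "smiles")))
  invisible(x)
}

#' Tanimoto similarity of two bit-vector fingerprints
#'
#' Intersection over union of the set bits; defined as 1 when both
#' vectors are all-zero.
#'
#' @param a,b logical vectors of equal length
#'   (e.g. [pubchem_fingerprint()] results).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Are two SMILES strings the same structure?
#'
#' Compares standard structure identifiers (InChI) of the two inputs;
#' full graph isomorphism up to tautomer-standardization of the
#' identifier layer.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @return logical flag.
#' @export
structures_identical <- function(smiles_a, smiles_b) {
  ia <- inchi(smiles_a)
  ib <- inchi(smiles_b)
  if (is.na(ia) || is.na(ib)) stop("unparseable SMILES in identity check")
  ia == ib
}
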