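# Low-level chemistry backend: all SMILES parsing, canonicalization,
# property calculation and SMARTS matching are delegated to Open Babel
# (ChemmineOB), with ChemmineR used to read V2000 connection tables.

#' Canonicalize SMILES strings
#'
#' Returns the project-wide canonical SMILES for each input string.
#' Canonical string equality under this function is the package's
#' definition of "same structure" wherever structures are compared.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` for unparseable input.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- suppressWarnings(try(
      ChemmineOB::convertFormat("SMI", "CAN", source = s),
      silent = TRUE
    ))
    if (inherits(out, "try-error")) return(NA_character_)
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Standard structure identifier (InChI) for a SMILES string
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of InChI strings; `NA` for unparseable input.
#' @export
inchi <- function(smiles) {
  vapply(smiles, function(s) {
    out <- suppressWarnings(try(
      ChemmineOB::convertFormat("SMI", "INCHI", source = s),
      silent = TRUE
    ))
    if (inherits(out, "try-error")) return(NA_character_)
    out <- sub("\n.*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Basic molecular properties of SMILES strings
#'
#' @param smiles character vector of SMILES strings.
#' @return tibble with columns `smiles`, `cansmi`, `formula`, `mol_weight`.
#' @export
mol_properties <- function(smiles) {
  rows <- lapply(smiles, function(s) {
    p <- suppressWarnings(try(
      ChemmineOB::forEachMol("SMILES", s, function(m) ChemmineOB::prop_OB(m)),
      silent = TRUE
    ))
    if (inherits(p, "try-error") || length(p) == 0) {
      return(tibble::tibble(smiles = s, cansmi = NA_character_,
                            formula = NA_character_, mol_weight = NA_real_))
    }
    p <- p[[1]]
    tibble::tibble(smiles = s, cansmi = p$cansmi, formula = p$formula,
                   mol_weight = p$MW)
  })
  dplyr::bind_rows(rows)
}

# Count SMARTS matches (unique matches) of several patterns on one molecule
# given in any Open Babel input format. Returns an integer vector.
smarts_counts <- function(input, patterns, format = "SMILES") {
  res <- ChemmineOB::forEachMol(format, input, function(m) {
    vapply(patterns, function(p) {
      as.numeric(ChemmineOB::smartsSearch_OB(list(m), p, uniqueMatches = TRUE))
    }, numeric(1))
  })
  if (length(res) == 0) stop("SMARTS matching failed: unparseable input")
  as.integer(res[[1]])
}

# ---- molecular graph ------------------------------------------------------

# Default valences used for implicit-hydrogen bookkeeping.
.default_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Se = 2, Br = 1, I = 1
)

#' Molecular graph of a SMILES string
#'
#' Parses a SMILES string (through Open Babel) into a plain heavy-atom
#' graph: a tibble of atoms (element, formal charge, isotope, implicit
#' hydrogen count) and a tibble of bonds (1-based endpoints, bond order).
#'
#' @param smiles a single SMILES string.
#' @return a list with elements `atoms` and `bonds` (class `mol_graph`).
#' @export
mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  sdf <- suppressWarnings(try(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
    silent = TRUE
  ))
  if (inherits(sdf, "try-error") || !nzchar(sdf) || !grepl("V2000", sdf)) {
    stop("unparseable SMILES: ", smiles, call. = FALSE)
  }
  graph_from_sdf_text(sdf)
}

# Parse the first molecule of a V2000 SDF text block into a mol_graph.
# The connection table is fixed-width, so it is read positionally.
graph_from_sdf_text <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  counts_line <- lines[4]
  natoms <- as.integer(substr(counts_line, 1, 3))
  nbonds <- as.integer(substr(counts_line, 4, 6))
  if (is.na(natoms)) stop("malformed V2000 block", call. = FALSE)
  atom_lines <- lines[4 + seq_len(natoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  charges <- integer(natoms)
  isotopes <- integer(natoms)
  for (ln in grep("^M  (CHG|ISO)", lines, value = TRUE)) {
    parts <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    k <- parts[1]
    idx <- parts[seq(2, by = 2, length.out = k)]
    val <- parts[seq(3, by = 2, length.out = k)]
    if (grepl("^M  CHG", ln)) charges[idx] <- val else isotopes[idx] <- val
  }
  if (is.na(nbonds) || nbonds == 0) {
    bonds <- tibble::tibble(from = integer(), to = integer(), order = integer())
  } else {
    bond_lines <- lines[4 + natoms + seq_len(nbonds)]
    bonds <- tibble::tibble(
      from = as.integer(substr(bond_lines, 1, 3)),
      to = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  }
  atoms <- tibble::tibble(element = elements, charge = charges,
                          isotope = isotopes)
  atoms$hcount <- implicit_hydrogens(atoms, bonds)
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

# Implicit hydrogen count per heavy atom from default valences; explicit
# hydrogens present as graph atoms reduce the implicit count via bond sums.
implicit_hydrogens <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    ord <- ifelse(bonds$order == 4, 1.5, bonds$order)  # 4 = aromatic in V2000
    for (i in seq_len(nrow(bonds))) {
      bsum[bonds$from[i]] <- bsum[bonds$from[i]] + ord[i]
      bsum[bonds$to[i]] <- bsum[bonds$to[i]] + ord[i]
    }
  }
  val <- unname(.default_valence[atoms$element])
  val[is.na(val)] <- 0
  eff <- val + ifelse(atoms$element %in% c("N", "P", "B"), atoms$charge,
                      -abs(atoms$charge))
  # hypervalent S/P (sulfone, phosphate): bump valence in steps of 2
  eff <- ifelse(atoms$element %in% c("S", "P", "Se") & bsum > eff,
                eff + 2 * ceiling((bsum - eff) / 2), eff)
  pmax(0L, as.integer(round(eff - bsum)))
}

# Serialize a mol_graph back to a V2000 SDF text block (no coordinates).
# With explicit_h = TRUE, implicit hydrogens are materialized as graph
# atoms so that SMARTS [#1] patterns can see them.
graph_to_sdf_text <- function(g, explicit_h = FALSE) {
  atoms <- g$atoms
  bonds <- g$bonds
  if (explicit_h) {
    nh <- atoms$hcount
    n0 <- nrow(atoms)
    for (i in seq_len(n0)) {
      if (nh[i] > 0) {
        for (k in seq_len(nh[i])) {
          atoms <- dplyr::bind_rows(atoms, tibble::tibble(
            element = "H", charge = 0L, isotope = 0L, hcount = 0L))
          bonds <- dplyr::bind_rows(bonds, tibble::tibble(
            from = i, to = nrow(atoms), order = 1L))
        }
      }
    }
  }
  na <- nrow(atoms); nb <- nrow(bonds)
  header <- c("", "  chemnmt", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atom_lines <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        atoms$element)
  bond_lines <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$from, bonds$to, bonds$order)
  } else character(0)
  extra <- character(0)
  chg <- which(atoms$charge != 0)
  if (length(chg) > 0) {
    extra <- c(extra, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, atoms$charge[chg]),
                                    collapse = "")))
  }
  iso <- which(atoms$isotope != 0)
  if (length(iso) > 0) {
    extra <- c(extra, paste0("M  ISO", sprintf("%3d", length(iso)),
                             paste0(sprintf("%4d%4d", iso, atoms$isotope[iso]),
                                    collapse = "")))
  }
  paste(c(header, atom_lines, bond_lines, extra, "M  END", "$$$$", ""),
        collapse = "\n")
}

# Canonical SMILES of a mol_graph (via Open Babel from the SDF block).
graph_to_smiles <- function(g) {
  if (nrow(g$atoms) == 0) return("")
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = graph_to_sdf_text(g))
  sub("[\t\n ].*$", "", out)
}

# Adjacency list (neighbor indices with bond orders) of a mol_graph.
graph_adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (i in seq_len(nrow(g$bonds))) {
      f <- g$bonds$from[i]; t <- g$bonds$to[i]; o <- g$bonds$order[i]
      adj[[f]] <- rbind(adj[[f]], c(t, o))
      adj[[t]] <- rbind(adj[[t]], c(f, o))
    }
  }
  adj
}
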