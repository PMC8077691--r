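# Key tables for the 881-bit PubChem/CACTVS-style substructure
# fingerprint. The layout follows the published keyset: section 1
# hierarchic element counts (bits 0-114), section 2 ring counts
# (115-262), section 3 simple atom pairs (263-326), section 4 simple
# atom nearest neighbors (327-415), section 5 detailed atom
# neighborhoods (416-459), section 6 simple SMARTS chains (460-712),
# section 7 complex SMARTS patterns (713-880). Patterns are stored in
# the keyset's own notation (element symbols; bonds "-" single, "="
# double, "#" triple, ":" aromatic, "~" any; "[#1]" explicit hydrogen)
# and compiled to SMARTS at load time.

# -- section 1: element count thresholds (115 bits) -------------------------
.fp_sec1 <- local({
  thresholds <- list(
    H = c(4, 8, 16, 32), Li = c(1, 2), B = c(1, 2, 4), C = c(2, 4, 8, 16, 32),
    N = c(1, 2, 4, 8), O = c(1, 2, 4, 8, 16), F = c(1, 2, 4), Na = c(1, 2),
    Si = c(1, 2), P = c(1, 2, 4), S = c(1, 2, 4, 8), Cl = c(1, 2, 4, 8),
    K = c(1, 2), Br = c(1, 2, 4), I = c(1, 2, 4)
  )
  singles <- c("Be", "Mg", "Al", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
               "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Kr", "Rb",
               "Sr", "Y", "Zr", "Nb", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd",
               "In", "Sn", "Sb", "Te", "Xe", "Cs", "Ba", "Lu", "Hf", "Ta",
               "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
               "La", "Ce", "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy",
               "Ho", "Er", "Tm", "Yb", "Tc", "U")
  elem <- c(rep(names(thresholds), lengths(thresholds)), singles)
  thr <- c(unlist(thresholds, use.names = FALSE), rep(1, length(singles)))
  data.frame(element = elem, threshold = thr, stringsAsFactors = FALSE)
})

# -- section 3: simple atom pairs, any bond (64 bits) -----------------------
.fp_sec3 <- c(
  "Li-H", "Li-Li", "Li-B", "Li-C", "Li-O", "Li-F", "Li-P", "Li-S", "Li-Cl",
  "B-H", "B-B", "B-C", "B-N", "B-O", "B-F", "B-Si", "B-P", "B-S", "B-Cl",
  "B-Br", "C-H", "C-C", "C-N", "C-O", "C-F", "C-Na", "C-Mg", "C-Al",
  "C-Si", "C-P", "C-S", "C-Cl", "C-As", "C-Se", "C-Br", "C-I", "N-H",
  "N-N", "N-O", "N-F", "N-Si", "N-P", "N-S", "N-Cl", "N-Br", "O-H", "O-O",
  "O-Mg", "O-Na", "O-Al", "O-Si", "O-P", "O-K", "F-P", "F-S", "Mg-H",
  "Mg-Mg", "Si-H", "Si-Si", "Si-Cl", "P-H", "P-P", "As-H", "As-As"
)

# -- section 4: simple atom nearest neighbors, "~" any bond, ":" aromatic ---
.fp_sec4 <- c(
  "C(~Br)(~C)", "C(~Br)(~C)(~C)", "C(~Br)(~H)", "C(~Br)(:C)", "C(~Br)(:N)",
  "C(~C)(~C)", "C(~C)(~C)(~C)", "C(~C)(~C)(~C)(~C)", "C(~C)(~C)(~C)(~H)",
  "C(~C)(~C)(~C)(~N)", "C(~C)(~C)(~C)(~O)", "C(~C)(~C)(~H)(~N)",
  "C(~C)(~C)(~H)(~O)", "C(~C)(~C)(~N)", "C(~C)(~C)(~O)", "C(~C)(~Cl)",
  "C(~C)(~Cl)(~H)", "C(~C)(~H)", "C(~C)(~H)(~N)", "C(~C)(~H)(~O)",
  "C(~C)(~H)(~O)(~O)", "C(~C)(~H)(~P)", "C(~C)(~H)(~S)", "C(~C)(~I)",
  "C(~C)(~N)", "C(~C)(~O)", "C(~C)(~S)", "C(~C)(~Si)", "C(~C)(:C)",
  "C(~C)(:C)(:C)", "C(~C)(:C)(:N)", "C(~C)(:N)", "C(~C)(:N)(:N)",
  "C(~Cl)(~Cl)", "C(~Cl)(~H)", "C(~Cl)(:C)", "C(~F)(~F)", "C(~F)(:C)",
  "C(~H)(~N)", "C(~H)(~O)", "C(~H)(~O)(~O)", "C(~H)(~S)", "C(~H)(~Si)",
  "C(~H)(:C)", "C(~H)(:C)(:C)", "C(~H)(:C)(:N)", "C(~H)(:N)",
  "C(~H)(~H)(~H)", "C(~N)(~N)", "C(~N)(:C)", "C(~N)(:C)(:C)",
  "C(~N)(:C)(:N)", "C(~N)(:N)", "C(~O)(~O)", "C(~O)(:C)", "C(~O)(:C)(:C)",
  "C(~S)(:C)", "C(~S)(:C)(:C)", "C(:C)(:C)", "C(:C)(:C)(:C)",
  "C(:C)(:C)(:N)", "C(:C)(:N)", "C(:C)(:N)(:N)", "C(:N)(:N)",
  "N(~C)(~C)", "N(~C)(~C)(~C)", "N(~C)(~C)(~H)", "N(~C)(~H)",
  "N(~C)(~H)(~N)", "N(~C)(~N)", "N(~C)(:C)", "N(~C)(:C)(:C)",
  "N(~H)(~N)", "N(~H)(:C)", "N(~H)(:C)(:C)", "N(:C)(:C)", "N(:C)(:C)(:C)",
  "O(~C)(~C)", "O(~C)(~H)", "O(~C)(~P)", "O(~H)(~S)", "O(:C)(:C)",
  "P(~C)(~C)", "P(~O)(~O)", "S(~C)(~C)", "S(~C)(~H)", "S(~C)(~O)",
  "S(~O)(~O)", "Si(~C)(~C)"
)

# -- section 5: detailed atom neighborhoods, explicit bond orders -----------
.fp_sec5 <- c(
  "C(-C)(=C)", "C(-C)(-C)(=C)", "C(-C)(=N)", "C(-C)(-C)(=N)", "C(-C)(=O)",
  "C(-C)(-C)(=O)", "C(-Cl)(=O)", "C(-H)(=C)", "C(-H)(-C)(=C)",
  "C(-H)(=N)", "C(-H)(=O)", "C(-H)(-C)(=O)", "C(-N)(=C)", "C(-N)(=N)",
  "C(-N)(=O)", "C(-N)(-C)(=O)", "C(-O)(=C)", "C(-O)(=N)", "C(-O)(=O)",
  "C(-O)(-C)(=O)", "C(-O)(-O)(=O)", "C(=C)(=C)", "C(#C)", "C(#N)",
  "C(-C)(#C)", "C(-C)(#N)", "C(-S)(=O)", "C(-S)(=N)", "C(-C)(-N)(=C)",
  "C(-C)(-O)(=C)", "N(-C)(=C)", "N(-C)(=N)", "N(-C)(=O)", "N(-H)(=C)",
  "N(-O)(=O)", "N(-N)(=C)", "N(=C)", "N(=N)", "N(=O)", "O(=C)",
  "O(=N)", "O(=S)", "S(=O)", "S(-O)(=O)"
)

# -- section 6: simple SMARTS chain patterns (253 bits) ---------------------
.fp_sec6 <- c(
  "C-C-C#C", "O-C-C=N", "O-C-C=O", "N:C-S-[#1]", "N-C-C=C", "O=S-C-C",
  "N#C-C=C", "C=N-N-C", "O=S-C-N", "S-S-C:C", "C:C-C=C", "S:C:C:C",
  "C:N:C-C", "S-C:N:C", "S:C:C:N", "S-C=N-C", "C-O-C=C", "N-N-C:C",
  "S-C=N-[#1]", "S-C-S-C", "C:S:C-C", "O-S-C:C", "C:N-C:C", "N-S-C:C",
  "N-C:N:C", "N:C:C:N", "N-C:N:N", "N-C=N-C", "N-C=N-[#1]", "N-C-S-C",
  "C-C-C=C", "C-N:C-[#1]", "N-C:O:C", "O=C-C:C", "O=C-C:N", "C-N-C:C",
  "N:N-C-[#1]", "O-C:C:N", "O-C=C-C", "N-C:C:N", "C-S-C:C", "Cl-C:C-C",
  "N-C=C-[#1]", "Cl-C:C-[#1]", "N:C:N-C", "Cl-C:C-O", "C-C:N:C",
  "C-C-S-C", "S=C-N-C", "Br-C:C-C", "[#1]-N-N-[#1]", "S=C-N-[#1]",
  "S:C:C-[#1]", "O-N-C-C", "N-N-C-C", "[#1]-C=C-[#1]", "N-N-C-N",
  "O=C-N-N", "N=C-N-C", "C=C-C:C", "C:N-C-[#1]", "C-N-N-[#1]",
  "N:C:C-C", "C-C=C-C", "Cl-C:C-Cl", "C:C:N-[#1]", "[#1]-N-C-[#1]",
  "Cl-C-C-Cl", "N:C-C:C", "S-C:C-C", "S-C:C-[#1]", "S-C:C-N",
  "S-C:C-O", "O=C-C-C", "O=C-C-N", "O=C-C-O", "N=C-C-C", "N=C-C-[#1]",
  "C-N-C-[#1]", "O-C:C-C", "O-C:C-[#1]", "O-C:C-N", "O-C:C-O",
  "N-C:C-C", "N-C:C-[#1]", "N-C:C-N", "O-C-C:C", "N-C-C:C",
  "Cl-C-C-C", "Cl-C-C-O", "C:C-C:C", "O=C-C=C", "Br-C-C-C",
  "N=C-C=C", "C=C-C-C", "N:C-O-[#1]", "O=N-C:C", "O-C-N-[#1]",
  "N-C-N-C", "Cl-C-C=O", "Br-C-C=O", "O-C-O-C", "C=C-C=C", "C:C-O-C",
  "O-C-C-N", "O-C-C-O", "N#C-C-C", "N-C-C-N", "C:C-C-C", "[#1]-C-O-[#1]",
  "N-C:C:C-C", "N-C:C:C:C", "C-N-C-C", "C-C-C-C", "O-C-C-C", "N-C-C-C",
  "[#1]-C-C-[#1]", "C-O-C-C", "N-C-O-C", "C-C-O-C", "N-C-C-O",
  "C-S-C-C", "Cl-C-C-N", "[#1]-C-C-C", "[#1]-C-C-N", "[#1]-C-C-O",
  "[#1]-C-N-[#1]", "[#1]-C-S-[#1]", "O=S-O-C", "O=S-N-C", "S-C-N-C",
  "O-P-O-C", "O=P-O-C", "O-C=C-[#1]", "C-C=N-C", "C-C=N-[#1]",
  "O-C=N-C", "C=C-N-C", "C=C-N-[#1]", "C=C-O-C", "C=C-O-[#1]",
  "C#C-C-C", "C#C-C-[#1]", "F-C-C-C", "F-C-C-F", "F-C-C=O", "I-C-C-C",
  "Br-C-C-N", "Br-C-C-O", "I-C:C-C", "F-C:C-C", "F-C:C-[#1]",
  "Br-C:C-[#1]", "I-C:C-[#1]", "Br-C:C-N", "F-C:C-N", "Br-C:C-O",
  "F-C:C-O", "C-C(-C)-C", "C-C(-C)(-C)-C", "N-C(-C)-C", "N-C(-N)=N",
  "O-C(-C)-C", "O-C(-O)-C", "O=C(-C)-C", "O=C(-N)-C", "O=C(-O)-C",
  "O=C(-N)-N", "O=C(-C)-N", "O=C(-C)-O", "S-C(-C)-C", "N-C(-C)=N",
  "O-C(-C)=C", "N-C(-C)=C", "Cl-C(-C)-C", "Br-C(-C)-C", "F-C(-F)-F",
  "Cl-C(-Cl)-Cl", "C-C(=O)-N-C", "C-C(=O)-O-C", "C-O-C(=O)-C",
  "N-C(=O)-N-C", "C-N-C(=O)-C", "C-C(=O)-C-C", "O-C(=O)-C-C",
  "N-C-C(=O)-C", "O=C-C-C-C", "O=C-C-C-N", "O=C-C-C-O", "N-C-C-C-C",
  "N-C-C-C-N", "N-C-C-C-O", "O-C-C-C-C", "O-C-C-C-O", "C-C-C-C-C",
  "C-C-C-C-[#1]", "Cl-C-C-C-C", "Br-C-C-C-C", "O-C-C=C-C", "N-C-C=C-C",
  "C-C-C=C-C", "C=C-C-C-C", "C:C-C-C-C", "C:C-C-C-[#1]", "C:C-C-C-N",
  "C:C-C-C-O", "C:C-C=C-C", "C:C:C-C-C", "C:C:C:C-C", "C:C:C:C:C",
  "N:C:C:C:C", "O-C:C:C:C", "N-C:C:C:C", "C-C:C:C:C", "[#1]-C:C:C-[#1]",
  "S-C:C:C:C", "Cl-C:C:C:C", "Br-C:C:C:C", "F-C:C:C:C", "C-C-N-C-C",
  "C-N(-C)-C", "O=C-N(-C)-C", "C-O-C-O-C", "N-C-N-C-C", "O-C-C-N-C",
  "C-C(-C)-N-C", "C-C(-C)-O-C", "C-C(-C)-C-O", "C-C(-C)-C-N",
  "C-C(-C)-C=O", "C-C(-C)=C-C", "C=C(-C)-C-C", "C-C(-N)-C-C",
  "C-C(-O)-C-C", "C-C(-Cl)-C-C", "O=C(-C)-C-C-C", "O=C(-C)-C-C-N",
  "O=C(-C)-C-C-O", "C-C-C(-C)-C-C", "N-C-C(-C)-C-C", "O-C-C(-C)-C-C",
  "C-C-C-C-C-C", "O-C-C-C-C-C", "N-C-C-C-C-C", "C-C-C-C-C=O",
  "C-C-C-C-C-O", "C-C-C-C-C-N", "C:C-O-C-C", "C:C-N-C-C", "O=S(=O)-C-C", "O=S(=O)-N-C", "O=S(=O)-C:C",
  "O=S(=O)-O-C"
)

# -- section 7: complex SMARTS patterns (168 bits) --------------------------
# Mostly substituted aromatic rings and branched skeletons; written as
# real SMARTS (lowercase aromatic) and used verbatim.
.fp_sec7 <- local({
  ring_subs <- c("C", "N", "O", "S", "Cl", "Br", "F", "I")
  two_sub <- function(a, b, pos) {
    sprintf("%sc1%sc(%s)%sc1", a,
            paste(rep("c", pos - 1), collapse = ""), b,
            paste(rep("c", 4 - pos), collapse = ""))
  }
  pats <- character(0)
  # mono-substituted benzene
  pats <- c(pats, sprintf("%s-c1ccccc1", ring_subs))
  # ortho / meta / para disubstitution over substituent pairs
  combos <- expand.grid(a = ring_subs, b = ring_subs,
                        stringsAsFactors = FALSE)
  combos <- combos[as.integer(factor(combos$a, ring_subs)) <=
                     as.integer(factor(combos$b, ring_subs)), ]
  for (pos in c(2, 3, 4)) {
    pats <- c(pats, mapply(function(a, b) {
      ring <- switch(as.character(pos),
        "2" = "c1c(%s)cccc1", "3" = "c1cc(%s)ccc1", "4" = "c1ccc(%s)cc1")
      sprintf(paste0("%s-", sprintf(ring, "-%s")), a, b)
    }, combos$a, combos$b))
  }
  # fused aromatic and aliphatic ring skeletons, branched chains
  pats <- c(pats,
    "c1ccc2ccccc2c1", "c1ccc2[nX2,nX3]ccc2c1", "c1ccc2occc2c1",
    "c1ccc2sccc2c1", "C1CCCCC1", "C1CCCC1", "C1CCCCCC1",
    "C1CCNCC1", "C1CCOCC1", "C1CCSCC1", "C1CCNC1", "C1CCOC1",
    "n1ccccc1", "n1ccncc1", "n1ccnc1", "o1cccc1", "s1cccc1",
    "[#6]1~[#6]~[#6]~[#6]~[#6]~[#6]~1~[#6]1~[#6]~[#6]~[#6]~[#6]~[#6]~1",
    "C-C(-C)(-C)-C", "C-C(-C)(-C)-C-C", "C-C(-C)(-N)-C", "C-C(-C)(-O)-C",
    "C-C(-C)(-C)-N", "C-C(-C)(-C)-O", "N-C(-C)(-C)-C-C",
    "O-C(-C)(-C)-C-C", "C-C(-C)-C(-C)-C", "C-C(-C)-C-C(-C)-C",
    "C-C(-O)-C(-C)-C", "C-C(-N)-C(-C)-C", "O=C(-C)-C(-C)-C",
    "O=C(-N)-C(-C)-C", "O=C(-O)-C(-C)-C", "C=C(-C)-C(-C)-C",
    "C-C(-C)-C(-C)=O", "C-C(-C)-C(-C)-O", "C-C(-C)-C(-C)-N",
    "O-C-C(-C)-C-O", "N-C-C(-C)-C-N", "O=C-C(-C)-C=O",
    "c1ccc(cc1)-c1ccccc1", "c1ccc(cc1)C-c1ccccc1", "c1ccc(cc1)O-c1ccccc1",
    "c1ccc(cc1)N-c1ccccc1", "c1ccc(cc1)S-c1ccccc1", "C1CC1",
    "C1CCCCCCC1", "O=C1CCCCC1", "O=C1CCCC1", "N-C1CCCCC1",
    "O-C1CCCCC1", "C-C1CCCCC1"
  )
  unique(pats)
})

.fp_element_numbers <- c(
  H = 1, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
  Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20,
  As = 33, Se = 34, Br = 35, I = 53
)

# Compile a key pattern written in the keyset notation into SMARTS.
.fp_pattern_to_smarts <- function(pattern) {
  if (grepl("^\\[#1\\]$", pattern)) return(pattern)
  out <- character(0)
  i <- 1L
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch %in% c("(", ")", "-", "=", "#", ":", "~")) {
      out <- c(out, ch); i <- i + 1L; next
    }
    if (ch == "[") {
      j <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      out <- c(out, substr(pattern, i, i + j - 1L))
      i <- i + j
      next
    }
    two <- substr(pattern, i, i + 1L)
    if (two %in% names(.fp_element_numbers)) {
      out <- c(out, sprintf("[#%d]", .fp_element_numbers[[two]]))
      i <- i + 2L
    } else if (ch == "H") {
      out <- c(out, "[#1]"); i <- i + 1L
    } else if (ch %in% names(.fp_element_numbers)) {
      out <- c(out, sprintf("[#%d]", .fp_element_numbers[[ch]]))
      i <- i + 1L
    } else {
      stop("cannot compile key pattern: ", pattern)
    }
  }
  paste(out, collapse = "")
}
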