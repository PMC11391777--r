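# Canonical residue tables shared across featurization, binding-site and
# surface modules. All tables are keyed by one-letter code; the 3-letter map
# serves the PDB-facing code.

#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y")

# Average (isotope-weighted) residue masses in Da; a chain adds one water.
AA_RESIDUE_MASS <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760)

WATER_MASS <- 18.0153

# Bjellqvist pKa set (as used by the ProtParam-style theoretical pI).
# Side chains: negative D,E,C,Y + C-terminus; positive H,K,R + N-terminus.
PKA_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
PKA_SIDE_POS <- c(H = 5.98, K = 10.00, R = 12.00)
PKA_CTERM <- 3.55
# N-terminal pKa depends on the first residue (Bjellqvist); 7.5 otherwise.
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70)
PKA_NTERM_DEFAULT <- 7.50

#' Default disjoint five-class side-chain partition
#'
#' The collapsed grouping used for the group-composition block of the
#' 25-dimensional sequence representation: acidic, basic, aromatic,
#' polar-uncharged and nonpolar-aliphatic classes that together cover all 20
#' canonical residues exactly once.
#'
#' @return Named list of character vectors of one-letter residue codes.
#' @export
aa_group_table <- function() {
  list(
    acidic    = c("D", "E"),
    basic     = c("K", "R", "H"),
    aromatic  = c("F", "W", "Y"),
    polar     = c("S", "T", "N", "Q", "C"),
    nonpolar  = c("G", "A", "V", "L", "I", "P", "M"))
}

#' Default dichotomy side-chain tables
#'
#' Six overlapping labels used for substrate-binding and surface residue
#' counts: positively/negatively charged, polar/non-polar, and
#' aliphatic/aromatic. Polar vs non-polar and aliphatic vs aromatic each
#' partition the 20 canonical residues; the charge labels cover only the five
#' charged residues. Histidine counts as both basic and aromatic.
#'
#' @return Named list of character vectors of one-letter residue codes.
#' @export
aa_dichotomy_table <- function() {
  list(
    positive  = c("K", "R", "H"),
    negative  = c("D", "E"),
    polar     = c("D", "E", "K", "R", "H", "N", "Q", "S", "T", "Y", "C"),
    nonpolar  = c("G", "A", "V", "L", "I", "P", "M", "F", "W"),
    aliphatic = c("G", "A", "V", "L", "I", "P", "M", "S", "T", "N",
                  "Q", "C", "D", "E", "K", "R"),
    aromatic  = c("F", "W", "Y", "H"))
}

# Bondi van der Waals radii (Angstrom) by element.
ELEMENT_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                    P = 1.80, SE = 1.90, CU = 1.40)
ELEMENT_RADIUS_DEFAULT <- 1.70

assert_canonical <- function(sequence, what = "sequence", allow_x = FALSE) {
  chars <- strsplit(sequence, "")[[1]]
  ok <- AA_ALPHABET
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0) {
    stop(sprintf("non-canonical residue(s) %s in %s",
                 paste(sQuote(bad), collapse = ", "), what), call. = FALSE)
  }
  invisible(chars)
}
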