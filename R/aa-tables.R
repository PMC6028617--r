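# Amino-acid bookkeeping shared across modules.
#
# State order for the substitution model follows the PAML convention
# (A R N D C Q E G H I L K M F P S T W Y V); composition tables are reported
# in the same order so vectors line up everywhere.

#' Canonical amino-acid state order
#'
#' One-letter codes of the 20 standard amino acids in the order used by all
#' model matrices, posterior vectors and composition tables in this package
#' (the PAML convention: A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_states()
aa_states <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# three-letter -> one-letter lookup (standard residues only)
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))

#' Convert three-letter residue names to one-letter codes
#'
#' Unknown or non-standard names map to `"X"`.
#'
#' @param res3 character vector of three-letter residue names.
#' @return Character vector of one-letter codes.
#' @export
aa_three_to_one <- function(res3) {
  out <- unname(.aa3to1[toupper(res3)])
  out[is.na(out)] <- "X"
  out
}

#' Convert one-letter codes to three-letter residue names
#'
#' @param res1 character vector of one-letter codes; unknowns map to `"UNK"`.
#' @return Character vector of three-letter names.
#' @export
aa_one_to_three <- function(res1) {
  out <- unname(.aa1to3[toupper(res1)])
  out[is.na(out)] <- "UNK"
  out
}

# Bondi-style van der Waals radii (Angstrom); unknown elements fall back to
# the carbon radius with a warning at assignment time.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.vdw_default <- 1.70

#' Van der Waals radii used for accessibility calculations
#'
#' Fixed published (Bondi-style) radii: C 1.70, N 1.55, O 1.52, S 1.80,
#' H 1.20, P 1.80 Angstrom. Elements outside this set are assigned the
#' default 1.70 Angstrom.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() .vdw_radii

# Assign radii from element symbols; warns once about unsupported elements.
.assign_radii <- function(element) {
  r <- .vdw_radii[toupper(element)]
  bad <- is.na(r)
  if (any(bad)) {
    warning(sprintf("%d atom(s) with unsupported element (%s); using default radius %.2f A",
                    sum(bad), paste(unique(element[bad]), collapse = ","), .vdw_default),
            call. = FALSE)
    r[bad] <- .vdw_default
  }
  unname(r)
}

# Backbone atom names; everything else on a standard residue is side chain.
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

# Side-chain atoms carrying formal charge at physiological pH, keyed as
# "RES|ATOM". Used by the VADAR-style polar/charged ASA split.
.charged_atoms <- c(
  "ASP|OD1", "ASP|OD2", "GLU|OE1", "GLU|OE2",
  "LYS|NZ", "ARG|NE", "ARG|NH1", "ARG|NH2",
  "HIS|ND1", "HIS|NE2"
)
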