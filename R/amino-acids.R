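# Amino-acid constants shared across modules.

#' Standard amino acids
#'
#' Three-letter and one-letter codes for the 20 standard amino acids, in the
#' conventional alphabetical (one-letter) order used throughout the package.
#'
#' @return `aa_codes()` returns a named character vector mapping three-letter
#'   codes to one-letter codes.
#' @export
aa_codes <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
}

#' @rdname aa_codes
#' @return `aa_one_letter()` returns the 20 one-letter codes, sorted.
#' @export
aa_one_letter <- function() sort(unname(aa_codes()))

# Backbone heavy atoms excluded from the side chain when locating fa.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Canonical terminal side-chain atom per residue type, used by the synthetic
# fixture generator to give planted/decoy residues a named fa atom.
TERMINAL_ATOM <- c(
  ALA = "CB",  ARG = "NH1", ASN = "ND2", ASP = "OD1", CYS = "SG",
  GLN = "NE2", GLU = "OE1", GLY = "CA",  HIS = "NE2", ILE = "CD1",
  LEU = "CD1", LYS = "NZ",  MET = "CE",  PHE = "CZ",  PRO = "CG",
  SER = "OG",  THR = "CG2", TRP = "CH2", TYR = "OH",  VAL = "CG1")

aa_to1 <- function(x) {
  codes <- aa_codes()
  out <- ifelse(nchar(x) == 1L, toupper(x), unname(codes[toupper(x)]))
  bad <- is.na(out) | !(out %in% aa_one_letter())
  if (any(bad)) {
    stop(sitematch_error("sitematch_type_error",
      sprintf("unknown amino-acid code(s): %s",
              paste(unique(x[bad]), collapse = ", "))))
  }
  out
}

aa_to3 <- function(x) {
  codes <- aa_codes()
  rev_codes <- stats::setNames(names(codes), unname(codes))
  out <- ifelse(nchar(x) == 3L, toupper(x), unname(rev_codes[toupper(x)]))
  bad <- is.na(out) | !(out %in% names(codes))
  if (any(bad)) {
    stop(sitematch_error("sitematch_type_error",
      sprintf("unknown amino-acid code(s): %s",
              paste(unique(x[bad]), collapse = ", "))))
  }
  out
}

# Classed conditions so the CLI can map error families to exit codes.
sitematch_error <- function(class, message, ...) {
  structure(class = c(class, "sitematch_error", "error", "condition"),
            list(message = message, call = sys.call(-1), ...))
}
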