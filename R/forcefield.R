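# United-atom parameter table and titratable-group definitions.

.ff_cache <- new.env(parent = emptyenv())

#' Load the united-atom radius/charge parameter table
#'
#' The shipped table assigns one radius and one neutral-form partial charge
#' per heavy atom of each standard residue (united-atom model: no non-polar
#' hydrogens; polar hydrogens are absorbed into their heavy atoms).  Each
#' neutral residue's charges sum to zero.  The ionized-form formal charge is
#' not part of this table: it is placed on the titratable group's terminal
#' atoms when a site model is built.
#'
#' @param path optional path to an alternative parameter file with columns
#'   `res`, `atom`, `radius`, `charge`.
#' @return data.frame with columns res, atom, radius, charge
#' @export
default_forcefield <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ff_cache$ff)) return(.ff_cache$ff)
    path <- system.file("extdata", "united_atoms.par", package = "fddh")
  }
  ff <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  stopifnot(all(c("res", "atom", "radius", "charge") %in% names(ff)))
  .ff_cache$ff <- ff
  ff
}

#' Model-compound pKa table for titratable groups
#'
#' Standard model-compound values for sidechains and chain termini, with the
#' ionized-form charge sign and the atoms over which the formal charge is
#' distributed.  All values are configurable by supplying an alternative
#' file.
#'
#' @param path optional path to a TSV with columns restype, pka, sign,
#'   charge_atoms (comma separated atom names)
#' @return data.frame
#' @export
model_pka_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ff_cache$pka)) return(.ff_cache$pka)
    path <- system.file("extdata", "model_pkas.tsv", package = "fddh")
  }
  tb <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("restype", "pka", "sign", "charge_atoms") %in% names(tb)))
  if (is.null(.ff_cache$pka)) .ff_cache$pka <- tb
  tb
}

# three-letter <-> one-letter residue codes
.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")
.AA1 <- setNames(names(.AA3), .AA3)

aa_three_to_one <- function(x) unname(.AA3[x])
aa_one_to_three <- function(x) unname(.AA1[x])
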