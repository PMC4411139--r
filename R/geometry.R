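# Internal-coordinate geometry: atom placement, peptide backbone and
# sidechain construction from chi angles.

.deg <- pi / 180

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Returns the position X bonded to `c3` with bond length `bond`, bond angle
#' X-c3-c2 `angle` (degrees) and torsion X-c3-c2-c1 `torsion` (degrees).
#'
#' @param c1,c2,c3 3-vectors of the three reference atoms
#' @param bond bond length in Angstrom
#' @param angle bond angle in degrees
#' @param torsion dihedral in degrees
#' @return 3-vector
#' @export
place_atom <- function(c1, c2, c3, bond, angle, torsion) {
  bc <- c3 - c2
  bc <- bc / sqrt(sum(bc^2))
  ab <- c2 - c1
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) stop("collinear reference atoms")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  ang <- angle * .deg
  tor <- torsion * .deg
  d <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c3 + d[1] * bc + d[2] * m + d[3] * n
}

#' Dihedral angle between four points
#' @param p1,p2,p3,p4 3-vectors
#' @return angle in degrees in (-180, 180]
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) / .deg
}

# Sidechain build table.  Each atom is placed by place_atom(a1, a2, a3, ...)
# i.e. bonded to a3, with torsion X-a3-a2-a1.  tors is either a fixed angle
# (numeric) or list(chi = k, offset = deg).
.topo_row <- function(atom, a1, a2, a3, bond, angle, tors) {
  list(atom = atom, a1 = a1, a2 = a2, a3 = a3, bond = bond, angle = angle,
       tors = tors)
}
.chi <- function(k, offset = 0) list(chi = k, offset = offset)

.SIDECHAIN_TOPO <- list(
  ALA = list(),
  GLY = list(),
  SER = list(.topo_row("OG", "N", "CA", "CB", 1.42, 110.8, .chi(1))),
  CYS = list(.topo_row("SG", "N", "CA", "CB", 1.81, 113.8, .chi(1))),
  THR = list(.topo_row("OG1", "N", "CA", "CB", 1.43, 109.6, .chi(1)),
             .topo_row("CG2", "N", "CA", "CB", 1.52, 110.5, .chi(1, -120))),
  VAL = list(.topo_row("CG1", "N", "CA", "CB", 1.52, 110.5, .chi(1)),
             .topo_row("CG2", "N", "CA", "CB", 1.52, 110.5, .chi(1, 122))),
  LEU = list(.topo_row("CG",  "N", "CA", "CB", 1.53, 116.3, .chi(1)),
             .topo_row("CD1", "CA", "CB", "CG", 1.52, 110.7, .chi(2)),
             .topo_row("CD2", "CA", "CB", "CG", 1.52, 110.7, .chi(2, 122))),
  ILE = list(.topo_row("CG1", "N", "CA", "CB", 1.53, 110.4, .chi(1)),
             .topo_row("CG2", "N", "CA", "CB", 1.52, 110.5, .chi(1, -122)),
             .topo_row("CD1", "CA", "CB", "CG1", 1.52, 113.9, .chi(2))),
  MET = list(.topo_row("CG", "N", "CA", "CB", 1.52, 114.1, .chi(1)),
             .topo_row("SD", "CA", "CB", "CG", 1.81, 112.7, .chi(2)),
             .topo_row("CE", "CB", "CG", "SD", 1.79, 100.9, .chi(3))),
  PRO = list(.topo_row("CG", "N", "CA", "CB", 1.49, 104.5, 30),
             .topo_row("CD", "CA", "CB", "CG", 1.51, 105.5, -35)),
  PHE = list(.topo_row("CG",  "N", "CA", "CB", 1.50, 113.8, .chi(1)),
             .topo_row("CD1", "CA", "CB", "CG", 1.39, 120.8, .chi(2)),
             .topo_row("CD2", "CA", "CB", "CG", 1.39, 120.8, .chi(2, 180)),
             .topo_row("CE1", "CB", "CG", "CD1", 1.39, 120.8, 180),
             .topo_row("CE2", "CB", "CG", "CD2", 1.39, 120.8, 180),
             .topo_row("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  TYR = list(.topo_row("CG",  "N", "CA", "CB", 1.51, 113.9, .chi(1)),
             .topo_row("CD1", "CA", "CB", "CG", 1.39, 120.8, .chi(2)),
             .topo_row("CD2", "CA", "CB", "CG", 1.39, 120.8, .chi(2, 180)),
             .topo_row("CE1", "CB", "CG", "CD1", 1.39, 121.2, 180),
             .topo_row("CE2", "CB", "CG", "CD2", 1.39, 121.2, 180),
             .topo_row("CZ",  "CG", "CD1", "CE1", 1.38, 119.6, 0),
             .topo_row("OH",  "CD1", "CE1", "CZ", 1.38, 119.9, 180)),
  TRP = list(.topo_row("CG",  "N", "CA", "CB", 1.50, 113.6, .chi(1)),
             .topo_row("CD1", "CA", "CB", "CG", 1.37, 126.9, .chi(2)),
             .topo_row("CD2", "CA", "CB", "CG", 1.43, 126.6, .chi(2, 180)),
             .topo_row("NE1", "CB", "CG", "CD1", 1.38, 110.2, 180),
             .topo_row("CE2", "CB", "CG", "CD2", 1.40, 107.2, 180),
             .topo_row("CE3", "CD1", "CG", "CD2", 1.40, 133.9, 180),
             .topo_row("CZ2", "CD1", "NE1", "CE2", 1.40, 130.1, 180),
             .topo_row("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 180),
             .topo_row("CH2", "NE1", "CE2", "CZ2", 1.37, 117.5, 180)),
  ASN = list(.topo_row("CG",  "N", "CA", "CB", 1.52, 112.6, .chi(1)),
             .topo_row("OD1", "CA", "CB", "CG", 1.23, 120.8, .chi(2)),
             .topo_row("ND2", "CA", "CB", "CG", 1.33, 116.4, .chi(2, 180))),
  GLN = list(.topo_row("CG",  "N", "CA", "CB", 1.52, 114.1, .chi(1)),
             .topo_row("CD",  "CA", "CB", "CG", 1.52, 112.6, .chi(2)),
             .topo_row("OE1", "CB", "CG", "CD", 1.23, 120.8, .chi(3)),
             .topo_row("NE2", "CB", "CG", "CD", 1.33, 116.4, .chi(3, 180))),
  ASP = list(.topo_row("CG",  "N", "CA", "CB", 1.52, 112.6, .chi(1)),
             .topo_row("OD1", "CA", "CB", "CG", 1.25, 118.4, .chi(2)),
             .topo_row("OD2", "CA", "CB", "CG", 1.25, 118.4, .chi(2, 180))),
  GLU = list(.topo_row("CG",  "N", "CA", "CB", 1.52, 114.1, .chi(1)),
             .topo_row("CD",  "CA", "CB", "CG", 1.52, 112.6, .chi(2)),
             .topo_row("OE1", "CB", "CG", "CD", 1.25, 118.4, .chi(3)),
             .topo_row("OE2", "CB", "CG", "CD", 1.25, 118.4, .chi(3, 180))),
  LYS = list(.topo_row("CG", "N", "CA", "CB", 1.52, 114.1, .chi(1)),
             .topo_row("CD", "CA", "CB", "CG", 1.52, 111.3, .chi(2)),
             .topo_row("CE", "CB", "CG", "CD", 1.52, 111.3, .chi(3)),
             .topo_row("NZ", "CG", "CD", "CE", 1.47, 112.0, .chi(4))),
  ARG = list(.topo_row("CG", "N", "CA", "CB", 1.52, 114.1, .chi(1)),
             .topo_row("CD", "CA", "CB", "CG", 1.52, 111.3, .chi(2)),
             .topo_row("NE", "CB", "CG", "CD", 1.46, 112.0, .chi(3)),
             .topo_row("CZ", "CG", "CD", "NE", 1.33, 124.2, .chi(4)),
             .topo_row("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
             .topo_row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)),
  HIS = list(.topo_row("CG",  "N", "CA", "CB", 1.50, 113.8, .chi(1)),
             .topo_row("ND1", "CA", "CB", "CG", 1.38, 122.7, .chi(2)),
             .topo_row("CD2", "CA", "CB", "CG", 1.36, 131.1, .chi(2, 180)),
             .topo_row("CE1", "CB", "CG", "ND1", 1.32, 109.2, 180),
             .topo_row("NE2", "CB", "CG", "CD2", 1.37, 107.2, 180))
)

# chi torsion flavours: sp3 rotors get staggered values, terminal sp2 groups
# get planar values (symmetric groups make 0/180 redundant but harmless).
.CHI_KIND <- list(
  SER = "3", CYS = "3", THR = "3", VAL = "3",
  LEU = c("3", "3"), ILE = c("3", "3"),
  MET = c("3", "3", "3"),
  PHE = c("3", "2"), TYR = c("3", "2"), TRP = c("3", "2"), HIS = c("3", "2"),
  ASN = c("3", "2"), ASP = c("3", "2"),
  GLN = c("3", "3", "2"), GLU = c("3", "3", "2"),
  LYS = c("3", "3", "3", "3"), ARG = c("3", "3", "3", "3")
)
.CHI_VALUES <- list("3" = c(-60, 60, 180), "2" = c(-90, 0, 90))

#' Number of chi angles for a residue type
#' @param restype three-letter code
#' @return integer (0 for residues without rotatable sidechains)
#' @export
n_chi <- function(restype) {
  k <- .CHI_KIND[[restype]]
  if (is.null(k)) 0L else length(k)
}

#' Discrete rotamer chi-angle library for a residue type
#'
#' Backbone-independent coarse chi grid: staggered values for sp3 rotors and
#' planar values for terminal sp2 groups (at most 81 rotamers per residue).
#'
#' @param restype three-letter residue code
#' @return matrix with one row per rotamer, one column per chi angle (degrees);
#'   a 1x0 matrix for residues without rotatable sidechains
#' @export
rotamer_chis <- function(restype) {
  kinds <- .CHI_KIND[[restype]]
  if (is.null(kinds)) return(matrix(numeric(0), nrow = 1, ncol = 0))
  vals <- lapply(kinds, function(k) .CHI_VALUES[[k]])
  as.matrix(expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE))[, rev(seq_along(kinds)),
                                                            drop = FALSE]
}

#' Canonical extended chi angles for a residue type
#' @param restype three-letter code
#' @return numeric vector (180 for sp3 rotors, 0 for terminal sp2 groups)
#' @export
extended_chis <- function(restype) {
  kinds <- .CHI_KIND[[restype]]
  if (is.null(kinds)) return(numeric(0))
  ifelse(kinds == "3", 180, 0)
}

# Build sidechain atom coordinates (beyond CB) for one residue given its
# backbone N/CA/CB positions and chi angles.  Returns named list of 3-vectors.
build_sidechain_coords <- function(restype, N, CA, CB, chis) {
  topo <- .SIDECHAIN_TOPO[[restype]]
  if (is.null(topo)) stop("no sidechain topology for residue type ", restype)
  pos <- list(N = N, CA = CA, CB = CB)
  out <- list()
  for (row in topo) {
    tors <- row$tors
    t_deg <- if (is.list(tors)) chis[tors$chi] + tors$offset else tors
    p <- place_atom(pos[[row$a1]], pos[[row$a2]], pos[[row$a3]],
                    row$bond, row$angle, t_deg)
    pos[[row$atom]] <- p
    out[[row$atom]] <- p
  }
  out
}

# Ideal CB position from backbone N, CA, C (L-amino acid).
ideal_cb <- function(N, CA, C) {
  place_atom(C, N, CA, 1.53, 110.5, 122.6)
}

#' Build an idealized peptide backbone
#'
#' Places N/CA/C/O (+CB) for a sequence of residues with fixed phi/psi/omega
#' torsions (default fully extended).  Used by the synthetic-structure
#' generators; comparative modelling never moves backbone atoms.
#'
#' @param sequence character vector of three-letter residue codes
#' @param phi,psi backbone torsions in degrees (default fully extended)
#' @return data.frame with columns resno, resname, atom, x, y, z
#' @export
build_backbone <- function(sequence, phi = -180, psi = 180) {
  n <- length(sequence)
  rows <- list()
  Nc <- c(0, 0, 0)
  CAc <- c(1.458, 0, 0)
  Cc <- CAc + 1.525 * c(cos((180 - 111) * .deg), sin((180 - 111) * .deg), 0)
  for (i in seq_len(n)) {
    res <- sequence[i]
    add <- function(atom, p) rows[[length(rows) + 1]] <<-
      data.frame(resno = i, resname = res, atom = atom,
                 x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    add("N", Nc); add("CA", CAc); add("C", Cc)
    Nn <- place_atom(Nc, CAc, Cc, 1.329, 116.2, psi)
    add("O", place_atom(Nc, CAc, Cc, 1.231, 120.5, psi + 180))
    if (res != "GLY") add("CB", ideal_cb(Nc, CAc, Cc))
    if (i < n) {
      CAn <- place_atom(CAc, Cc, Nn, 1.458, 121.7, 180)
      Cn <- place_atom(Cc, Nn, CAn, 1.525, 111.0, phi)
      Nc <- Nn; CAc <- CAn; Cc <- Cn
    }
  }
  do.call(rbind, rows)
}
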