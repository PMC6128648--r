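## Idealized peptide construction.
##
## Backbones are grown atom-by-atom in the natural extension reference
## frame with standard bond lengths/angles; side chains come from a compact
## internal-coordinate template table (all rotatable chi angles extended at
## 180 degrees, rings planar).  These idealized geometries back the
## synthetic fixtures and the naive mutant builder; they make no claim to
## being energy-minimised conformers.

## Backbone geometry (lengths Angstrom, angles degrees)
BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

## Side-chain internal coordinates.  Each atom is placed by torsion
## a-b-c-X, angle b-c-X, bond c-X; references name earlier atoms of the
## same residue.  Chi torsions are extended (180) except where ring closure
## or sp2 branching dictates otherwise.
SIDECHAIN_IC <- list(
  ALA = NULL,
  GLY = NULL,
  SER = list(c("OG",  "N",  "CA", "CB", 1.417, 110.8, 180)),
  CYS = list(c("SG",  "N",  "CA", "CB", 1.808, 113.8, 180)),
  THR = list(c("OG1", "N",  "CA", "CB", 1.433, 109.6, 180),
             c("CG2", "N",  "CA", "CB", 1.521, 110.5, -60)),
  VAL = list(c("CG1", "N",  "CA", "CB", 1.527, 110.5, 180),
             c("CG2", "N",  "CA", "CB", 1.527, 110.5, -60)),
  LEU = list(c("CG",  "N",  "CA", "CB", 1.530, 116.3, 180),
             c("CD1", "CA", "CB", "CG", 1.521, 110.7, 180),
             c("CD2", "CA", "CB", "CG", 1.521, 110.7, 60)),
  ILE = list(c("CG1", "N",  "CA", "CB", 1.530, 110.4, 180),
             c("CG2", "N",  "CA", "CB", 1.521, 110.5, -60),
             c("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  MET = list(c("CG",  "N",  "CA", "CB", 1.520, 114.1, 180),
             c("SD",  "CA", "CB", "CG", 1.807, 112.7, 180),
             c("CE",  "CB", "CG", "SD", 1.789, 100.9, 180)),
  PRO = list(c("CG",  "N",  "CA", "CB", 1.495, 104.5, 15),
             c("CD",  "CA", "CB", "CG", 1.507, 106.1, -15)),
  PHE = list(c("CG",  "N",  "CA", "CB", 1.500, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.390, 120.7, 90),
             c("CD2", "CA", "CB", "CG", 1.390, 120.7, -90),
             c("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
             c("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, 0)),
  TYR = list(c("CG",  "N",  "CA", "CB", 1.500, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.390, 120.7, 90),
             c("CD2", "CA", "CB", "CG", 1.390, 120.7, -90),
             c("CE1", "CB", "CG", "CD1", 1.390, 120.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.390, 120.0, 180),
             c("CZ",  "CG", "CD1", "CE1", 1.390, 120.0, 0),
             c("OH",  "CD1", "CE1", "CZ", 1.376, 120.0, 180)),
  TRP = list(c("CG",  "N",  "CA", "CB", 1.500, 113.6, 180),
             c("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
             c("CD2", "CA", "CB", "CG", 1.433, 126.7, -90),
             c("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
             c("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
             c("CE3", "CB", "CG", "CD2", 1.400, 133.9, 0),
             c("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
             c("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180),
             c("CH2", "CD2", "CE2", "CZ2", 1.400, 117.5, 0)),
  HIS = list(c("CG",  "N",  "CA", "CB", 1.500, 113.8, 180),
             c("ND1", "CA", "CB", "CG", 1.378, 122.7, 90),
             c("CD2", "CA", "CB", "CG", 1.354, 131.1, -90),
             c("CE1", "CB", "CG", "ND1", 1.320, 109.2, 180),
             c("NE2", "CB", "CG", "CD2", 1.374, 107.2, 180)),
  ASP = list(c("CG",  "N",  "CA", "CB", 1.516, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.249, 118.4, 0),
             c("OD2", "CA", "CB", "CG", 1.249, 118.4, 180)),
  ASN = list(c("CG",  "N",  "CA", "CB", 1.516, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
             c("ND2", "CA", "CB", "CG", 1.328, 116.4, 180)),
  GLU = list(c("CG",  "N",  "CA", "CB", 1.520, 114.1, 180),
             c("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.249, 118.4, 0),
             c("OE2", "CB", "CG", "CD", 1.249, 118.4, 180)),
  GLN = list(c("CG",  "N",  "CA", "CB", 1.520, 114.1, 180),
             c("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
             c("NE2", "CB", "CG", "CD", 1.328, 116.4, 180)),
  LYS = list(c("CG",  "N",  "CA", "CB", 1.520, 114.1, 180),
             c("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
             c("CE",  "CB", "CG", "CD", 1.520, 111.3, 180),
             c("NZ",  "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = list(c("CG",  "N",  "CA", "CB", 1.520, 114.1, 180),
             c("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
             c("NE",  "CB", "CG", "CD", 1.461, 112.0, 180),
             c("CZ",  "CG", "CD", "NE", 1.329, 124.2, 180),
             c("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180))
)

## Build side-chain heavy atoms for residue `aa3` given backbone N/CA/C
## coordinates.  Returns a data.frame (elety, element, x, y, z); empty for
## glycine.
build_sidechain <- function(aa3, n, ca, c) {
  if (aa3 == "GLY") {
    return(data.frame(elety = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE))
  }
  pos <- list(N = n, CA = ca, C = c)
  pos$CB <- place_cb(n, ca, c)
  rows <- SIDECHAIN_IC[[aa3]]
  for (r in rows) {
    pos[[r[1]]] <- place_atom(pos[[r[2]]], pos[[r[3]]], pos[[r[4]]],
                              as.numeric(r[5]), as.numeric(r[6]),
                              as.numeric(r[7]))
  }
  names_out <- setdiff(names(pos), c("N", "CA", "C"))
  xyz <- do.call(rbind, pos[names_out])
  data.frame(elety = names_out,
             element = element_from_name(names_out),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Build an idealized peptide with fixed backbone dihedrals
#'
#' Grows a single chain with the given phi/psi (and omega = 180) using
#' standard bond lengths and angles, then attaches idealized side chains.
#'
#' @param sequence character vector of one-letter amino acids (a single
#'   string is also accepted), length >= 2.
#' @param phi,psi backbone dihedrals in degrees (recycled along the chain).
#' @param chain chain identifier.
#' @param id structure label.
#' @param start_resno author number of the first residue.
#' @return a `protein_structure`.
#' @examples
#' hx <- build_peptide("AAAAAAAAAA", phi = -57, psi = -47)
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, chain = "A",
                          id = "peptide", start_resno = 1L) {
  if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  if (!all(is_standard_aa1(sequence))) {
    stop("invalid sequence: ",
         paste(sequence[!is_standard_aa1(sequence)], collapse = ", "))
  }
  nres <- length(sequence)
  if (nres < 2) stop("sequence must have at least 2 residues")
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)

  N <- CA <- C <- vector("list", nres)
  ## first residue seeds the frame
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(BB$n_ca, 0, 0)
  ang <- deg2rad(BB$ang_n_ca_c)
  C[[1]] <- CA[[1]] + BB$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(nres - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                             BB$c_n, BB$ang_ca_c_n, psi[i])
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]],
                              BB$n_ca, BB$ang_c_n_ca, 180)  # omega trans
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]],
                             BB$ca_c, BB$ang_n_ca_c, phi[i + 1])
  }

  out <- vector("list", nres)
  for (i in seq_len(nres)) {
    ## carbonyl O anti to the next N (or to psi continuation at the C terminus)
    o <- place_atom(N[[i]], CA[[i]], C[[i]], BB$c_o, BB$ang_ca_c_o,
                    psi[i] + 180)
    aa3 <- aa_three(sequence[i])
    bb <- data.frame(elety = c("N", "CA", "C", "O"),
                     element = c("N", "C", "C", "O"),
                     x = c(N[[i]][1], CA[[i]][1], C[[i]][1], o[1]),
                     y = c(N[[i]][2], CA[[i]][2], C[[i]][2], o[2]),
                     z = c(N[[i]][3], CA[[i]][3], C[[i]][3], o[3]),
                     stringsAsFactors = FALSE)
    sc <- build_sidechain(aa3, N[[i]], CA[[i]], C[[i]])
    res <- rbind(bb, sc)
    res$chain <- chain
    res$resno <- start_resno + i - 1L
    res$insert <- ""
    res$resid <- aa3
    res$het <- FALSE
    out[[i]] <- res
  }
  atoms <- do.call(rbind, out)
  new_structure(atoms[, c("chain", "resno", "insert", "resid", "elety",
                          "element", "x", "y", "z", "het")],
                id = id)
}

## Apply a rigid-body transform (rotation matrix R then translation t).
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- atom_xyz(structure) %*% t(R)
  structure$atoms$x <- xyz[, 1] + t[1]
  structure$atoms$y <- xyz[, 2] + t[2]
  structure$atoms$z <- xyz[, 3] + t[3]
  structure
}
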