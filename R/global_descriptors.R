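## Global-structure (G) descriptors: whole-protein properties computed on
## the wild type and on a naively built mutant; the block carries the
## deltas (mutant - wild type).
##
## The formulas here are documented in-package substitutes for the
## proprietary whole-protein property calculators used in commercial
## modelling suites; only their roles (shape, surface, charge, transport
## surrogates) are reproduced, so individual values are relative
## quantities and only the deltas are meaningful as descriptors.

## Mean residue volumes (Angstrom^3; Chothia-style crystal volumes)
RESIDUE_VOLUME <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
  E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
  Y = 193.6, V = 140.0
)

#' Build a naive point mutant of a structure
#'
#' Replaces the side chain of the residue at (chain, position) by an
#' idealized template for the mutant amino acid, superposed on the
#' backbone N-CA-C frame.  The backbone (including the carbonyl O) and all
#' other residues are untouched; no repacking or minimisation is done.
#'
#' @param structure a stripped `protein_structure`.
#' @param chain,position residue address.
#' @param mut one-letter mutant amino acid.
#' @return a `protein_structure` of the mutant (a plain copy when
#'   `mut` equals the wild-type residue).
#' @export
build_naive_mutant <- function(structure, chain, position, mut) {
  mut <- toupper(mut)
  if (!is_standard_aa1(mut)) stop("non-standard mutant amino acid: ", mut)
  idx <- find_residue(structure, chain, position)
  at <- structure$atoms
  aa3_old <- at$resid[idx[1]]
  aa3_new <- aa_three(mut)

  bb_sel <- idx[at$elety[idx] %in% BACKBONE_ATOMS]
  need <- c("N", "CA", "C")
  if (!all(need %in% at$elety[bb_sel])) {
    stop("cannot mutate ", chain, position, ": backbone atom(s) missing")
  }
  if (aa3_new == aa3_old) {
    return(structure)
  }
  g <- function(name) {
    i <- bb_sel[at$elety[bb_sel] == name][1]
    c(at$x[i], at$y[i], at$z[i])
  }
  sc <- build_sidechain(aa3_new, g("N"), g("CA"), g("C"))

  keep <- setdiff(seq_len(nrow(at)), setdiff(idx, bb_sel))
  atoms <- at[keep, , drop = FALSE]
  res_rows <- which(atoms$chain == chain & atoms$resno == position)
  atoms$resid[res_rows] <- aa3_new
  if (nrow(sc) > 0) {
    tmpl <- atoms[rep(res_rows[1], nrow(sc)), , drop = FALSE]
    tmpl$elety <- sc$elety
    tmpl$element <- sc$element
    tmpl$x <- sc$x; tmpl$y <- sc$y; tmpl$z <- sc$z
    atoms <- rbind(atoms, tmpl)
  }
  new_structure(atoms, id = paste0(structure$id, "_", aa_one(aa3_old),
                                   position, mut),
                source = structure$source)
}

## ---- per-structure global properties -------------------------------------

gyration_tensor <- function(xyz, w) {
  com <- colSums(xyz * w) / sum(w)
  d <- sweep(xyz, 2, com)
  t(d * w) %*% d / sum(w)
}

#' Whole-protein properties of a single structure
#'
#' @param structure a stripped `protein_structure`.
#' @param sasa optional precomputed [compute_sasa()] result.
#' @param probe_radius,n_points SASA parameters.
#' @param hydrophobic_elements elements counted as apolar surface.
#' @return named numeric vector of global properties (see [g_block()]).
#' @export
global_properties <- function(structure, sasa = NULL, probe_radius = 1.4,
                              n_points = 960,
                              hydrophobic_elements = c("C", "S")) {
  at <- structure$atoms
  xyz <- atom_xyz(structure)
  mass <- ATOMIC_MASS[at$element]
  mass[is.na(mass)] <- ATOMIC_MASS[["C"]]

  gt <- gyration_tensor(xyz, mass)
  ev <- sort(eigen(gt, symmetric = TRUE, only.values = TRUE)$values)
  rg <- sqrt(sum(diag(gt)))
  ecc <- if (ev[3] > 1e-12) 1 - ev[1] / ev[3] else 0

  if (is.null(sasa)) {
    sasa <- compute_sasa(structure, probe_radius = probe_radius,
                         n_points = n_points)
  }
  asa <- sasa$total
  hydro_sa <- sum(sasa$per_atom[at$element %in% hydrophobic_elements])

  rt <- residue_table(structure)
  vol <- sum(RESIDUE_VOLUME[rt$aa], na.rm = TRUE)

  ch <- structure_charges(structure)
  net <- sum(ch$q)
  com <- colSums(xyz * mass) / sum(mass)
  if (nrow(ch$pos) > 0) {
    dip_vec <- colSums(ch$pos * ch$q) - net * com
    dipole <- vnorm(dip_vec)
  } else dipole <- 0

  ss <- assign_secondary_structure(structure)
  helix_ratio <- mean(ss == "helix")

  total_mass <- sum(mass)
  rh <- 0.77 * rg                      # compact-globule approximation
  frictional <- rh
  diffusion <- if (rh > 1e-9) 1 / rh else NA_real_
  sedimentation <- if (rh > 1e-9) total_mass / rh else NA_real_
  mobility <- if (rh > 1e-9) net / rh else NA_real_

  c(radiusOfGyration = rg,
    eccentricity = ecc,
    accessibleSurfaceArea = asa,
    hydrophobicSurfaceArea = hydro_sa,
    hydrophilicSurfaceArea = asa - hydro_sa,
    volume = vol,
    netCharge = net,
    dipoleMoment = dipole,
    helixRatio = helix_ratio,
    hydrodynamicRadius = rh,
    diffusionCoefficient = diffusion,
    frictionalCoefficient = frictional,
    sedimentationConstant = sedimentation,
    mobility = mobility)
}

## Charged-group point charges: side-chain centroids for D/E/K/R plus the
## chain termini (+1 on the first N, -1 on the last carboxyl C of each
## chain).  Formal charges at pH 7, matching the aa_properties charge
## scale.
structure_charges <- function(structure) {
  at <- structure$atoms
  rt <- residue_table(structure)
  pos <- NULL
  q <- numeric(0)
  centroid <- function(sel) {
    colMeans(cbind(at$x[sel], at$y[sel], at$z[sel]))
  }
  side_atoms <- list(D = c("OD1", "OD2"), E = c("OE1", "OE2"),
                     K = "NZ", R = c("NH1", "NH2", "NE"))
  side_q <- c(D = -1, E = -1, K = 1, R = 1)
  key <- residue_key(at)
  for (i in seq_len(nrow(rt))) {
    aa <- rt$aa[i]
    if (is.na(aa) || !aa %in% names(side_atoms)) next
    sel <- which(key == rt$key[i] & at$elety %in% side_atoms[[aa]])
    if (length(sel) == 0) next
    pos <- rbind(pos, centroid(sel))
    q <- c(q, side_q[[aa]])
  }
  for (ch in unique(rt$chain)) {
    rows <- which(rt$chain == ch)
    nterm <- which(key == rt$key[rows[1]] & at$elety == "N")
    cterm <- which(key == rt$key[rows[length(rows)]] & at$elety == "C")
    if (length(nterm)) { pos <- rbind(pos, centroid(nterm[1])); q <- c(q, 1) }
    if (length(cterm)) { pos <- rbind(pos, centroid(cterm[1])); q <- c(q, -1) }
  }
  if (is.null(pos)) pos <- matrix(numeric(0), 0, 3)
  list(pos = pos, q = q)
}

#' Global (G) descriptor block: mutant minus wild type
#'
#' @param wt,mut `protein_structure`s aligned residue-for-residue except
#'   for the mutated side chain.
#' @param ... passed to [global_properties()].
#' @return named numeric vector of deltas, names prefixed `d_`.
#' @export
g_block <- function(wt, mut, ...) {
  if (nrow(residue_table(wt)) != nrow(residue_table(mut))) {
    stop("wild-type and mutant structures have different residue counts")
  }
  pw <- global_properties(wt, ...)
  pm <- global_properties(mut, ...)
  d <- pm - pw
  names(d) <- paste0("d_", names(pw))
  d
}
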