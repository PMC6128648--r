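## Secondary-structure assignment from backbone hydrogen-bond patterns, in
## the Kabsch-Sander style: the amide H is inferred from the preceding
## peptide C=O, an electrostatic energy is computed for candidate
## N-H...O=C bonds, and helix / beta / turn classes follow from the i->i+4,
## ladder, and i->i+3 bond patterns.

HB_ENERGY_CUTOFF <- -0.5   # kcal/mol
HB_Q1Q2_F <- 0.084 * 332   # coupled partial charges times electrostatic factor

## Extract backbone coordinate arrays per residue; NA rows where missing.
backbone_coords <- function(structure) {
  at <- structure$atoms
  rt <- residue_table(structure)
  key <- residue_key(at)
  get <- function(name) {
    m <- matrix(NA_real_, nrow(rt), 3)
    sel <- at$elety == name
    idx <- match(key[sel], rt$key)
    m[idx, ] <- cbind(at$x[sel], at$y[sel], at$z[sel])
    m
  }
  list(rt = rt, N = get("N"), CA = get("CA"), C = get("C"), O = get("O"))
}

## Pairwise backbone H-bond matrix: hb[i, j] TRUE when the carbonyl of
## residue i accepts the amide H of residue j.
hbond_matrix <- function(structure) {
  bb <- backbone_coords(structure)
  rt <- bb$rt
  n <- nrow(rt)
  ## infer H on N(j) from the previous residue's C=O: N-H parallel to O->C
  H <- matrix(NA_real_, n, 3)
  for (j in seq_len(n)[-1]) {
    same_chain <- rt$chain[j - 1] == rt$chain[j]
    if (!same_chain) next
    if (anyNA(bb$C[j - 1, ]) || anyNA(bb$O[j - 1, ]) || anyNA(bb$N[j, ])) next
    H[j, ] <- bb$N[j, ] + unit(bb$C[j - 1, ] - bb$O[j - 1, ])
  }
  ## prolines have no amide H
  H[rt$resid == "PRO", ] <- NA_real_

  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {         # acceptor C=O of residue i
    if (anyNA(bb$C[i, ]) || anyNA(bb$O[i, ])) next
    for (j in seq_len(n)) {       # donor N-H of residue j
      if (i == j || anyNA(H[j, ]) || anyNA(bb$N[j, ])) next
      ## adjacent in sequence on the same chain cannot H-bond
      if (rt$chain[i] == rt$chain[j] && abs(i - j) < 2) next
      r_on <- vnorm(bb$O[i, ] - bb$N[j, ])
      if (r_on > 5.2) next
      r_ch <- vnorm(bb$C[i, ] - H[j, ])
      r_oh <- vnorm(bb$O[i, ] - H[j, ])
      r_cn <- vnorm(bb$C[i, ] - bb$N[j, ])
      e <- HB_Q1Q2_F * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      hb[i, j] <- e < HB_ENERGY_CUTOFF
    }
  }
  list(hb = hb, rt = rt)
}

#' Assign secondary structure from backbone hydrogen bonds
#'
#' Hydrogen bonds are detected with the electrostatic criterion
#' E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) < -0.5 kcal/mol, with
#' the amide hydrogen placed 1 Angstrom from N along the preceding C=O
#' direction.  Runs of i -> i+4 bonds give helix, bridge ladder patterns
#' give beta, isolated i -> i+3 bonds give turn, everything else
#' (including chain termini and residues with missing backbone atoms) is
#' coil.  Priority when classes overlap: helix > beta > turn.
#'
#' @param structure a stripped `protein_structure` with backbone N, CA, C,
#'   O present for assignable residues.
#' @return character vector (one per residue, in [residue_table()] order)
#'   with values `"helix"`, `"beta"`, `"turn"`, `"coil"`, named by residue
#'   key.
#' @export
assign_secondary_structure <- function(structure) {
  hbm <- hbond_matrix(structure)
  hb <- hbm$hb
  rt <- hbm$rt
  n <- nrow(rt)
  ss <- rep("coil", n)

  same_chain_run <- function(i, j) {
    i >= 1 && j <= n && all(rt$chain[i:j] == rt$chain[i])
  }
  turn4 <- vapply(seq_len(n), function(i) {
    i + 4 <= n && same_chain_run(i, i + 4) && hb[i, i + 4]
  }, logical(1))
  turn3 <- vapply(seq_len(n), function(i) {
    i + 3 <= n && same_chain_run(i, i + 3) && hb[i, i + 3]
  }, logical(1))

  ## helix: two consecutive i->i+4 turns cover residues i+1 .. i+4
  helix <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    if (turn4[i] && turn4[i + 1]) helix[(i + 1):(i + 4)] <- TRUE
  }

  ## beta bridges (parallel and antiparallel), sequence separation > 2 or
  ## different chains
  beta <- rep(FALSE, n)
  seq_ok <- function(i, j) rt$chain[i] != rt$chain[j] || abs(i - j) > 2
  for (i in seq_len(n)[-c(1, n)]) {
    for (j in seq_len(n)[-c(1, n)]) {
      if (i == j || !seq_ok(i, j)) next
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      para <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      if (anti || para) beta[i] <- TRUE
    }
  }

  ## i->i+3 turns
  turn <- rep(FALSE, n)
  for (i in which(turn3)) turn[(i + 1):(i + 3)] <- TRUE

  ss[turn] <- "turn"
  ss[beta] <- "beta"
  ss[helix] <- "helix"
  stats::setNames(ss, rt$key)
}

SS_CLASSES <- c("helix", "beta", "coil", "turn")
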