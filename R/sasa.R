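## Shrake-Rupley solvent-accessible surface area.
##
## Each atom is represented by a sphere of radius r_vdw + probe sampled
## with a deterministic golden-spiral point set; the accessible fraction is
## the share of points not inside any neighbouring atom's inflated sphere.

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param structure a stripped `protein_structure` (heavy atoms only).
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param n_points number of sphere sample points per atom (>= 16;
#'   default 960).
#' @param radii named van der Waals radius table, see
#'   [default_vdw_radii()].
#' @return an object of class `sasa_result`: list with `per_atom`
#'   (Angstrom^2 per atom, in structure atom order), `per_residue` (named
#'   by residue key, summed over the residue's atoms) and `total`.
#' @examples
#' hx <- build_peptide("AAAAA")
#' compute_sasa(hx, n_points = 120)$total
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                         radii = default_vdw_radii()) {
  stopifnot(n_points >= 16)
  atoms <- structure$atoms
  n <- nrow(atoms)
  xyz <- atom_xyz(structure)
  R <- vdw_radius(atoms$element, radii) + probe_radius

  ## exact duplicates get zero area (and do not occlude their twin)
  dup <- duplicated(round(xyz, 6))
  if (any(dup)) {
    warning(sum(dup), " duplicate atom position(s); duplicates assigned area 0")
  }

  pts <- sphere_points(n_points)
  area <- numeric(n)
  live <- which(!dup)
  ## neighbour candidates via a coarse distance cut
  maxR <- max(R)
  for (i in live) {
    d2 <- (xyz[live, 1] - xyz[i, 1])^2 + (xyz[live, 2] - xyz[i, 2])^2 +
      (xyz[live, 3] - xyz[i, 3])^2
    nb <- live[d2 > 1e-12 & d2 < (R[i] + maxR)^2]
    nb <- nb[sqrt((xyz[nb, 1] - xyz[i, 1])^2 + (xyz[nb, 2] - xyz[i, 2])^2 +
                    (xyz[nb, 3] - xyz[i, 3])^2) < R[i] + R[nb]]
    p <- pts * R[i]
    p1 <- p[, 1] + xyz[i, 1]; p2 <- p[, 2] + xyz[i, 2]; p3 <- p[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      inside <- (p1 - xyz[j, 1])^2 + (p2 - xyz[j, 2])^2 +
        (p3 - xyz[j, 3])^2 < R[j]^2
      acc <- acc & !inside
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }

  key <- residue_key(atoms)
  per_res <- tapply(area, factor(key, levels = unique(key)), sum)
  structure(list(per_atom = area,
                 per_residue = per_res[!is.na(per_res)],
                 total = sum(area)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, %d residues, total %.1f A^2\n",
              length(x$per_atom), length(x$per_residue), x$total))
  invisible(x)
}

## --------------------------------------------------------------------------
## Reference (free-residue) total areas: SASA of the central residue of an
## extended Gly-X-Gly tripeptide, including its backbone atoms.

#' Reference total area of a free residue
#'
#' Returns "TotalArea": the solvent-accessible surface area of amino acid
#' `aa` including backbone atoms, in the reference state of the central
#' residue of an extended Gly-X-Gly tripeptide.  Values come from a table
#' shipped with the package; [regenerate_reference_areas()] recomputes it.
#'
#' @param aa one-letter amino-acid code (vectorised).
#' @param table optional replacement table as returned by
#'   [regenerate_reference_areas()].
#' @return numeric vector of areas (Angstrom^2).
#' @export
reference_total_area <- function(aa, table = NULL) {
  if (is.null(table)) table <- shipped_reference_areas()
  aa <- toupper(aa)
  if (!all(is_standard_aa1(aa))) {
    stop("unknown amino acid(s): ",
         paste(unique(aa[!is_standard_aa1(aa)]), collapse = ", "))
  }
  unname(table[aa])
}

shipped_reference_areas <- function() {
  path <- system.file("extdata", "reference_areas.tsv",
                      package = "thermoforest")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$total_area, tab$aa)
}

#' Regenerate the reference total-area table
#'
#' Builds an extended Gly-X-Gly tripeptide for each amino acid X, computes
#' Shrake-Rupley SASA and sums the central residue's atoms.
#'
#' @param probe_radius,n_points,radii passed to [compute_sasa()].
#' @return named numeric vector (20 amino acids) of areas in Angstrom^2.
#' @export
regenerate_reference_areas <- function(probe_radius = 1.4, n_points = 960,
                                       radii = default_vdw_radii()) {
  vapply(AA1, function(aa) {
    tri <- build_peptide(c("G", aa, "G"), phi = -139, psi = 135,
                         id = paste0("GXG_", aa))
    s <- compute_sasa(tri, probe_radius = probe_radius, n_points = n_points,
                      radii = radii)
    unname(s$per_residue[2])
  }, numeric(1))
}
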