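## Local-environment (L) descriptors of the wild-type residue: solvent
## accessibility derived areas and the secondary-structure class.

#' Local (L) descriptor block for one residue
#'
#' Computes, for the residue at (chain, position):
#' * `totalArea` -- reference SASA of the free residue including backbone
#'   ([reference_total_area()]);
#' * `buriedArea` -- `totalArea` minus the residue's observed SASA in the
#'   structure (the area occluded by protein);
#' * `hydrophobicArea` -- observed SASA contributed by apolar (carbon and
#'   sulfur) atoms;
#' * `hydrophobicRatio` -- `hydrophobicArea / observedArea` (0 when the
#'   residue is fully buried);
#' * `fractionBuried` -- `buriedArea / totalArea`, clipped to \[0, 1\];
#' * `secondaryStructure` -- class from [assign_secondary_structure()].
#'
#' @param structure a stripped `protein_structure`.
#' @param chain,position residue address (author numbering).
#' @param sasa optional precomputed [compute_sasa()] result for
#'   `structure`; computed on the fly if `NULL`.
#' @param ss optional precomputed [assign_secondary_structure()] result.
#' @param probe_radius,n_points,radii SASA parameters (used when `sasa`
#'   is `NULL`).
#' @param hydrophobic_elements elements counted as apolar.
#' @return a `local_descriptors` list with the fields above plus
#'   `observed_area` and a `missing_atoms` flag (TRUE when side-chain
#'   heavy atoms expected for the residue type are absent).
#' @export
local_block <- function(structure, chain, position, sasa = NULL, ss = NULL,
                        probe_radius = 1.4, n_points = 960,
                        radii = default_vdw_radii(),
                        hydrophobic_elements = c("C", "S")) {
  idx <- find_residue(structure, chain, position)
  at <- structure$atoms
  aa3 <- at$resid[idx[1]]
  aa <- aa_one(aa3)
  if (is.na(aa)) stop("residue ", aa3, " at ", chain, position,
                      " is not a standard amino acid; strip the structure first")

  if (is.null(sasa)) {
    sasa <- compute_sasa(structure, probe_radius = probe_radius,
                         n_points = n_points, radii = radii)
  }
  if (is.null(ss)) ss <- assign_secondary_structure(structure)

  key <- paste(chain, position, at$insert[idx[1]], sep = "|")
  observed <- unname(sasa$per_residue[key])
  total <- reference_total_area(aa)
  buried <- total - observed
  hydro <- sum(sasa$per_atom[idx][at$element[idx] %in% hydrophobic_elements])
  ratio <- if (observed > 0) hydro / observed else 0
  frac <- min(1, max(0, buried / total))

  expected <- expected_heavy_atoms(aa3)
  missing_atoms <- !all(expected %in% at$elety[idx])
  if (missing_atoms) {
    warning("residue ", chain, position, " (", aa3, ") is missing heavy atoms: ",
            paste(setdiff(expected, at$elety[idx]), collapse = ", "))
  }

  structure(list(
    aa = aa,
    totalArea = total,
    observed_area = observed,
    buriedArea = buried,
    hydrophobicArea = hydro,
    hydrophobicRatio = ratio,
    fractionBuried = frac,
    secondaryStructure = unname(ss[key]),
    missing_atoms = missing_atoms
  ), class = "local_descriptors")
}

expected_heavy_atoms <- function(aa3) {
  sc <- if (aa3 %in% c("ALA", "GLY")) character(0) else
    vapply(SIDECHAIN_IC[[aa3]], `[`, character(1), 1)
  cb <- if (aa3 == "GLY") character(0) else "CB"
  c("N", "CA", "C", "O", cb, sc)
}

#' @export
print.local_descriptors <- function(x, ...) {
  cat(sprintf(
    "<local_descriptors> %s: total %.1f, observed %.1f, fracBuried %.3f, %s\n",
    x$aa, x$totalArea, x$observed_area, x$fractionBuried,
    x$secondaryStructure))
  invisible(x)
}

## Numeric L-block row used by the descriptor-matrix assembler: the five
## named areas/ratios plus a one-hot secondary-structure encoding.
local_block_row <- function(lb) {
  ssv <- as.numeric(SS_CLASSES == lb$secondaryStructure)
  names(ssv) <- paste0("ss_", SS_CLASSES)
  c(totalArea = lb$totalArea,
    buriedArea = lb$buriedArea,
    hydrophobicArea = lb$hydrophobicArea,
    hydrophobicRatio = lb$hydrophobicRatio,
    fractionBuried = lb$fractionBuried,
    ssv)
}
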